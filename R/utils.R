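`%||%` <- function(a, b) if (is.null(a)) b else a

.tt_cache <- new.env(parent = emptyenv())

# let data.table [] syntax work from this package without attaching it
.datatable.aware <- TRUE

#' Collapse runs of whitespace and trim ends
#' @param x character vector
#' @return character vector of the same length
#' @keywords internal
#' @noRd
squish <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

stopf <- function(fmt, ..., class = NULL) {
  stop(structure(
    class = c(class, "titletrends_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be TRUE or FALSE", name)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stopf("`%s` must be a single integer >= %d", name, min)
  }
  invisible(as.integer(x))
}

pkg_file <- function(...) {
  path <- system.file(..., package = "titletrends", mustWork = FALSE)
  if (!nzchar(path)) stopf("packaged file not found: %s", file.path(...))
  path
}

# Restore the caller's RNG state on exit so seeded generators do not
# perturb the enclosing session.
with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
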