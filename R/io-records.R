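#' Write records as line-delimited JSON
#'
#' One JSON object per line with keys `pmid`, `journal`, `year`, `title`,
#' `pub_types`.
#'
#' @param records a record tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records_jsonl <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(jsonlite::toJSON(
      list(pmid = records$pmid[i], journal = records$journal[i],
           year = records$year[i], title = records$title[i],
           pub_types = as.list(records$pub_types[[i]])),
      auto_unbox = TRUE
    ), con)
  }
  invisible(path)
}

#' Read records written by [write_records_jsonl()]
#' @param path input path.
#' @return A record tibble.
#' @export
read_records_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  objs <- lapply(lines, jsonlite::fromJSON)
  tibble::tibble(
    pmid = vapply(objs, `[[`, character(1), "pmid"),
    journal = vapply(objs, `[[`, character(1), "journal"),
    year = vapply(objs, function(o) as.integer(o$year), integer(1)),
    title = vapply(objs, `[[`, character(1), "title"),
    pub_types = lapply(objs, function(o) as.character(unlist(o$pub_types)))
  )
}

#' Write records as TSV (pub_types pipe-joined)
#' @param records a record tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records_tsv <- function(records, path) {
  df <- data.frame(
    pmid = records$pmid, journal = records$journal, year = records$year,
    title = records$title,
    pub_types = vapply(records$pub_types, paste, character(1),
                       collapse = "|")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read records written by [write_records_tsv()]
#' @param path input path.
#' @return A record tibble.
#' @export
read_records_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8",
                          colClasses = c("character", "character",
                                         "integer", "character",
                                         "character"))
  tibble::tibble(
    pmid = df$pmid, journal = df$journal, year = df$year,
    title = df$title,
    pub_types = strsplit(df$pub_types, "|", fixed = TRUE)
  )
}
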