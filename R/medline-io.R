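#' Parse MEDLINE/PubMed XML into article records
#'
#' Reads a `PubmedArticleSet` document (the dialect returned by NCBI
#' E-utilities `efetch`) and emits one validated record per citation that
#' carries both a non-empty title and a resolvable publication year.
#' Citations lacking either, or lacking any publication type, are skipped
#' and tallied in the parse report; duplicated PMIDs keep the first
#' occurrence and are tallied too.
#'
#' Year resolution uses `PubDate/Year` when present, otherwise the first
#' 4-digit run inside `MedlineDate` (so a range such as "1979-1980"
#' resolves to 1979). Inline markup inside `<ArticleTitle>` (italics,
#' sub/superscripts) is flattened to its text content and internal
#' whitespace collapsed to single spaces; a trailing period is kept.
#'
#' @param x path to an XML file, or a length-one character string
#'   containing the XML document itself.
#' @return A [tibble::tibble] with columns `pmid` (character), `journal`
#'   (character), `year` (integer), `title` (character) and `pub_types`
#'   (list of character vectors), carrying the parse report as attribute
#'   `"parse_report"` (see [parse_report()]).
#' @examples
#' xml <- paste0(
#'   "<PubmedArticleSet><PubmedArticle><MedlineCitation>",
#'   "<PMID>1</PMID><Article>",
#'   "<Journal><Title>JAMA</Title><JournalIssue><PubDate>",
#'   "<Year>1980</Year></PubDate></JournalIssue></Journal>",
#'   "<ArticleTitle>A study</ArticleTitle>",
#'   "<PublicationTypeList><PublicationType>Journal Article",
#'   "</PublicationType></PublicationTypeList>",
#'   "</Article></MedlineCitation></PubmedArticle></PubmedArticleSet>"
#' )
#' parse_medline_xml(xml)
#' @export
parse_medline_xml <- function(x) {
  doc <- tryCatch(
    xml2::read_xml(x),
    error = function(e) {
      stopf("malformed XML: %s", conditionMessage(e),
            class = "titletrends_xml_error")
    }
  )
  root <- xml2::xml_name(doc)
  if (root != "PubmedArticleSet") {
    stopf("unexpected XML root element <%s>; expected <PubmedArticleSet>",
          root, class = "titletrends_xml_error")
  }

  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  n_in <- length(arts)
  skipped <- c(no_title = 0L, no_year = 0L, no_pub_type = 0L)

  pmid <- character(0); journal <- character(0); year <- integer(0)
  title <- character(0); pub_types <- list()

  for (art in arts) {
    ttl <- squish(xml2::xml_text(
      xml2::xml_find_first(art, ".//Article/ArticleTitle")
    ))
    if (is.na(ttl) || !nzchar(ttl)) {
      skipped[["no_title"]] <- skipped[["no_title"]] + 1L
      next
    }
    yr <- resolve_year(art)
    if (is.na(yr)) {
      skipped[["no_year"]] <- skipped[["no_year"]] + 1L
      next
    }
    pt <- xml2::xml_text(xml2::xml_find_all(
      art, ".//Article/PublicationTypeList/PublicationType"
    ))
    pt <- pt[nzchar(pt)]
    if (length(pt) == 0L) {
      skipped[["no_pub_type"]] <- skipped[["no_pub_type"]] + 1L
      next
    }
    id <- xml2::xml_text(xml2::xml_find_first(art, ".//MedlineCitation/PMID"))
    jr <- squish(xml2::xml_text(
      xml2::xml_find_first(art, ".//Article/Journal/Title")
    ))
    pmid <- c(pmid, if (is.na(id)) NA_character_ else id)
    journal <- c(journal, if (is.na(jr)) NA_character_ else jr)
    year <- c(year, yr)
    title <- c(title, ttl)
    pub_types <- c(pub_types, list(pt))
  }

  recs <- tibble::tibble(
    pmid = pmid, journal = journal, year = year,
    title = title, pub_types = pub_types
  )

  n_dup <- 0L
  if (nrow(recs) > 0L) {
    dup <- !is.na(recs$pmid) & duplicated(recs$pmid)
    n_dup <- sum(dup)
    recs <- recs[!dup, , drop = FALSE]
  }

  attr(recs, "parse_report") <- list(
    n_citations = n_in,
    n_records = nrow(recs),
    n_skipped = sum(skipped),
    skipped_reasons = as.list(skipped),
    n_duplicate_pmids = n_dup
  )
  recs
}

resolve_year <- function(art) {
  y <- xml2::xml_text(xml2::xml_find_first(
    art, ".//Journal/JournalIssue/PubDate/Year"
  ))
  if (!is.na(y) && grepl("^[0-9]{4}$", trimws(y))) {
    return(as.integer(trimws(y)))
  }
  md <- xml2::xml_text(xml2::xml_find_first(
    art, ".//Journal/JournalIssue/PubDate/MedlineDate"
  ))
  if (!is.na(md)) {
    m <- regmatches(md, regexpr("[0-9]{4}", md))
    if (length(m) == 1L) return(as.integer(m))
  }
  NA_integer_
}

#' Retrieve the parse report attached to a record set
#'
#' @param records output of [parse_medline_xml()].
#' @return A list with counts: `n_citations`, `n_records`, `n_skipped`,
#'   `skipped_reasons` (per-reason counts) and `n_duplicate_pmids`.
#' @export
parse_report <- function(records) {
  attr(records, "parse_report")
}

#' Construct a journal/year/publication-type cohort filter
#'
#' @param journals character vector of canonical journal names (`NULL`
#'   keeps all journals).
#' @param year_min,year_max inclusive calendar-year bounds.
#' @param include_types,exclude_types character vectors of MEDLINE
#'   publication-type names (prose aliases are accepted, see
#'   [pub_type_config()]). They must not overlap.
#' @return An object of class `cohort_filter`.
#' @export
cohort_filter <- function(journals = NULL, year_min = 1976L, year_max = 2015L,
                          include_types = character(0),
                          exclude_types = character(0)) {
  year_min <- assert_count(year_min, "year_min", min = 0L)
  year_max <- assert_count(year_max, "year_max", min = 0L)
  if (year_min > year_max) stopf("year_min (%d) > year_max (%d)", year_min, year_max)
  inc <- canonical_pub_type(include_types)
  exc <- canonical_pub_type(exclude_types)
  if (length(intersect(tolower(inc), tolower(exc))) > 0L) {
    stopf("include_types and exclude_types overlap: %s",
          paste(intersect(tolower(inc), tolower(exc)), collapse = ", "))
  }
  structure(
    list(journals = journals, year_min = year_min, year_max = year_max,
         include_types = inc, exclude_types = exc),
    class = "cohort_filter"
  )
}

#' Publication-type configuration shipped with the package
#'
#' Returns the include/exclude MEDLINE publication-type lists used to
#' select clinical-trial reports, together with the prose-name alias table
#' and a version string. The defaults include clinical trials of any phase
#' (randomized, pragmatic, controlled) and exclude secondary or
#' non-research types (comments, editorials, letters, reviews, case
#' reports, ...).
#'
#' @param path optional path to an alternative YAML config with keys
#'   `version`, `include`, `exclude`, `aliases`.
#' @return A list with elements `version`, `include`, `exclude`, `aliases`.
#' @export
pub_type_config <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.tt_cache$pub_type_config)) return(.tt_cache$pub_type_config)
    path <- pkg_file("extdata", "clinical_trial_types.yaml")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  cfg <- yaml::read_yaml(path)
  for (k in c("version", "include", "exclude")) {
    if (is.null(cfg[[k]])) stopf("publication-type config lacks key '%s'", k)
  }
  cfg$include <- unlist(cfg$include)
  cfg$exclude <- unlist(cfg$exclude)
  cfg$aliases <- as.list(cfg$aliases %||% list())
  if (cache) .tt_cache$pub_type_config <- cfg
  cfg
}

# Case-insensitive canonicalisation of publication-type names via the
# shipped alias table; unknown names pass through unchanged.
canonical_pub_type <- function(x, cfg = NULL) {
  if (length(x) == 0L) return(character(0))
  cfg <- cfg %||% pub_type_config()
  alias <- cfg$aliases
  canon <- c(cfg$include, cfg$exclude)
  out <- vapply(x, function(nm) {
    key <- tolower(trimws(nm))
    if (!is.null(alias[[key]])) return(alias[[key]])
    hit <- canon[tolower(canon) == key]
    if (length(hit) >= 1L) hit[[1L]] else trimws(nm)
  }, character(1), USE.NAMES = FALSE)
  unique(out)
}

#' Filter records to a journal/year cohort
#'
#' Keeps exactly the records whose journal is in `f$journals` (all
#' journals when `NULL`) and whose year lies in `[f$year_min, f$year_max]`
#' (inclusive). Order is preserved; an empty result is valid.
#'
#' @param records a record tibble as returned by [parse_medline_xml()].
#' @param f a [cohort_filter()].
#' @return The filtered record tibble.
#' @export
filter_cohort <- function(records, f) {
  stopifnot(inherits(f, "cohort_filter"))
  keep <- records$year >= f$year_min & records$year <= f$year_max
  if (!is.null(f$journals)) {
    keep <- keep & records$journal %in% f$journals
  }
  records[which(keep), , drop = FALSE]
}

#' Select clinical-trial reports by publication type
#'
#' A record is kept iff its publication types intersect the inclusion list
#' and do not intersect the exclusion list. Matching is case-insensitive
#' against canonical MEDLINE names, with prose aliases (e.g. "randomized
#' clinical trial") resolved through the shipped alias table. The
#' selection is idempotent and order-preserving.
#'
#' @param records a record tibble.
#' @param f a [cohort_filter()] whose `include_types`/`exclude_types` are
#'   populated; defaults to the shipped clinical-trial configuration over
#'   the record set's full year range.
#' @return The selected records, with attribute `"trial_selection"`: a
#'   list with `n_input`, `n_pass_inclusion`, `n_removed_by_exclusion`
#'   (named per exclusion type; a record failing several rules counts
#'   under each) and `n_kept`.
#' @export
select_clinical_trials <- function(records, f = NULL) {
  if (is.null(f)) {
    cfg <- pub_type_config()
    f <- cohort_filter(
      year_min = if (nrow(records)) min(records$year) else 0L,
      year_max = if (nrow(records)) max(records$year) else 0L,
      include_types = cfg$include, exclude_types = cfg$exclude
    )
  }
  stopifnot(inherits(f, "cohort_filter"))
  if (length(f$include_types) == 0L) {
    stopf("cohort filter has no include_types; cannot select trials")
  }
  inc <- tolower(f$include_types)
  exc <- tolower(f$exclude_types)

  cfg <- pub_type_config()
  types_lc <- lapply(records$pub_types,
                     function(p) tolower(canonical_pub_type(p, cfg)))
  pass_inc <- vapply(types_lc, function(p) any(p %in% inc), logical(1))
  hit_exc <- lapply(types_lc, function(p) intersect(p, exc))
  has_exc <- lengths(hit_exc) > 0L

  removed <- setNames(integer(length(exc)), f$exclude_types)
  for (h in hit_exc[pass_inc]) {
    for (t in h) {
      nm <- f$exclude_types[match(t, exc)]
      removed[[nm]] <- removed[[nm]] + 1L
    }
  }

  keep <- pass_inc & !has_exc
  out <- records[which(keep), , drop = FALSE]
  attr(out, "trial_selection") <- list(
    n_input = nrow(records),
    n_pass_inclusion = sum(pass_inc),
    n_removed_by_exclusion = as.list(removed),
    n_kept = nrow(out)
  )
  out
}

#' Cohort accounting: per-journal included counts and their total
#'
#' Sums per-journal counts of included titles into the cohort total, the
#' basic sanity check every selection report must satisfy.
#'
#' @param counts a data frame with columns `journal` and `n_included`, or
#'   `NULL` to use the packaged reference counts for the five-journal
#'   clinical-trial cohort (1976-1980 and 2011-2015 windows).
#' @return A list with `per_journal` (the input tibble) and `total`.
#' @export
cohort_accounting <- function(counts = NULL) {
  if (is.null(counts)) {
    counts <- read.csv(pkg_file("extdata", "included_trial_counts.csv"),
                       stringsAsFactors = FALSE)
  }
  if (!all(c("journal", "n_included") %in% names(counts))) {
    stopf("counts must have columns 'journal' and 'n_included'")
  }
  if (any(counts$n_included < 0)) stopf("negative included count")
  list(
    per_journal = tibble::as_tibble(counts),
    total = sum(counts$n_included)
  )
}
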