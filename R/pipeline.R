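#' Run the full title-trends pipeline from a single config
#'
#' Wires the stages `simulate -> parse -> count -> trend -> classify ->
#' contrast -> report` in order, writing every intermediate artifact plus
#' a run manifest into the output directory. Any stage failure aborts
#' with a diagnostic naming the stage. Reruns with the same config and
#' seed reproduce the outputs exactly.
#'
#' The config is a YAML file (or equivalent named list) with keys:
#' \describe{
#'   \item{seed}{integer, used by the simulate stage (required when
#'     simulating).}
#'   \item{stages}{character vector, a prefix-closed subset of the stage
#'     order above; default all stages.}
#'   \item{synthetic}{arguments passed to [synthetic_spec()] (e.g.
#'     `years`, `articles_per_year`).}
#'   \item{xml}{path(s) to existing MEDLINE XML when not simulating.}
#'   \item{cohort}{`journals`, `year_min`, `year_max` for
#'     [filter_cohort()].}
#'   \item{trend}{`fdr_threshold`, `top_k`, `low_freq_threshold` for
#'     [screen()].}
#'   \item{classify}{`eras` (named year pairs) for the era contrast.}
#' }
#' Unknown keys are a validation error (exit status 2 in the CLI
#' wrapper), as is a missing input file (exit status 3).
#'
#' @param config path to a YAML config file, or a named list.
#' @param out_dir output directory (default `config$out_dir`, falling
#'   back to `"titletrends_out"`).
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stopf("config file not found: %s", config,
            class = "titletrends_input_error")
    }
    config <- yaml::read_yaml(config)
  }
  known <- c("seed", "stages", "out_dir", "synthetic", "xml", "cohort",
             "trend", "classify")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "),
          class = "titletrends_config_error")
  }
  all_stages <- c("simulate", "parse", "count", "trend", "classify",
                  "contrast", "report")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) {
    stopf("unknown stage(s): %s", paste(bad, collapse = ", "),
          class = "titletrends_config_error")
  }

  out_dir <- out_dir %||% config$out_dir %||% "titletrends_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message("[titletrends] ", msg)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", stage, conditionMessage(e),
            class = "titletrends_stage_error")
    })
  }

  records <- NULL
  truth <- NULL
  outputs <- character(0)

  if ("simulate" %in% stages) {
    run_stage("simulate", {
      syn_args <- config$synthetic %||% list()
      if (!is.null(syn_args$years)) {
        syn_args$years <- seq(syn_args$years[[1]],
                              syn_args$years[[length(syn_args$years)]])
      }
      if (is.null(syn_args$seed)) syn_args$seed <- config$seed
      if (is.null(syn_args$seed)) {
        stopf("simulate stage needs a seed",
              class = "titletrends_config_error")
      }
      spec <- do.call(synthetic_spec, syn_args)
      gen <- generate_corpus(spec)
      truth <- gen$truth
      xml_path <- file.path(out_dir, "corpus.xml")
      write_corpus(gen$records, xml_path)
      jsonlite::write_json(
        list(true_slopes = as.list(truth$true_slopes),
             true_labels = as.list(truth$true_labels)),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA
      )
      outputs <- c(outputs, xml_path, file.path(out_dir, "truth.json"))
      config$xml <- xml_path
      note("simulate: %d records -> %s", nrow(gen$records), xml_path)
    })
  }

  if ("parse" %in% stages) {
    records <- run_stage("parse", {
      if (is.null(config$xml)) {
        stopf("no XML input configured", class = "titletrends_input_error")
      }
      paths <- Sys.glob(config$xml)
      if (length(paths) == 0L) {
        stopf("no XML file matches '%s'", config$xml,
              class = "titletrends_input_error")
      }
      parts <- lapply(paths, parse_medline_xml)
      rec <- combine_records(parts)
      rep_tot <- Reduce(function(a, b) Map(function(x, y) {
        if (is.list(x)) Map(`+`, x, y) else x + y
      }, a, b), lapply(parts, parse_report))
      if (!is.null(config$cohort)) {
        f <- cohort_filter(
          journals = config$cohort$journals,
          year_min = config$cohort$year_min %||% min(rec$year),
          year_max = config$cohort$year_max %||% max(rec$year)
        )
        rec <- filter_cohort(rec, f)
      }
      write_records_tsv(rec, file.path(out_dir, "records.tsv"))
      jsonlite::write_json(rep_tot, file.path(out_dir, "parse_report.json"),
                           auto_unbox = TRUE)
      outputs <- c(outputs, file.path(out_dir, c("records.tsv",
                                                 "parse_report.json")))
      note("parse: %d records from %d file(s), %d skipped",
           nrow(rec), length(paths), rep_tot$n_skipped)
      rec
    })
  }

  tabs <- list()
  if ("count" %in% stages) {
    run_stage("count", {
      if (is.null(records)) stopf("count stage needs parsed records")
      cfg <- tokenizer_config()
      for (ord in c(1L, 2L)) {
        tab <- build_frequency_table(records, ord, cfg)
        nm <- if (ord == 1L) "monograms" else "bigrams"
        tabs[[nm]] <- tab
        write_freq_table(tab, file.path(out_dir, paste0(nm, ".tsv")))
        outputs <- c(outputs, file.path(out_dir, paste0(nm, ".tsv")))
        note("count: %s, %d terms over %d years", nm, nrow(tab$counts),
             length(tab$years))
      }
    })
  }

  reports <- list()
  if ("trend" %in% stages) {
    run_stage("trend", {
      if (length(tabs) == 0L) stopf("trend stage needs count tables")
      tr <- config$trend %||% list()
      span <- diff(range(tabs$monograms$years))
      for (nm in names(tabs)) {
        scr <- screen(
          tabs[[nm]],
          fdr_threshold = tr$fdr_threshold %||% 0.01,
          k = tr$top_k %||% 20L,
          low_freq_threshold = tr$low_freq_threshold %||% 1e-4
        )
        reports[[nm]] <- scr
        write_screen_report(scr, out_dir, prefix = nm, year_span = span)
        note("trend: %s, %d/%d significant at FDR < %g", nm,
             sum(scr$results$q < scr$fdr_threshold), nrow(scr$results),
             scr$fdr_threshold)
      }
    })
  }

  labels <- NULL
  if ("classify" %in% stages) {
    labels <- run_stage("classify", {
      if (is.null(records)) stopf("classify stage needs parsed records")
      trials <- select_clinical_trials(records)
      rules <- rule_set()
      lab <- classify_title(trials$title, rules)
      lab$title_id <- trials$pmid
      lab$year <- trials$year
      lab$journal <- trials$journal
      out <- lab[, c("title_id", "title", "patient_centric",
                     "rules_version")]
      out$evidence <- vapply(lab$evidence, paste, character(1),
                             collapse = "|")
      utils::write.table(out, file.path(out_dir, "labels.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         fileEncoding = "UTF-8")
      outputs <- c(outputs, file.path(out_dir, "labels.tsv"))
      note("classify: %d trial titles, %d patient-centric (%s)",
           nrow(lab), sum(lab$patient_centric), rules$version)
      lab
    })
  }

  contrast <- NULL
  if ("contrast" %in% stages) {
    contrast <- run_stage("contrast", {
      if (is.null(labels)) stopf("contrast stage needs classified labels")
      eras <- config$classify$eras %||%
        list(early = c(1976, 1980), late = c(2011, 2015))
      in_era <- function(y, e) y >= e[[1]] & y <= e[[2]]
      early <- labels[in_era(labels$year, eras$early), ]
      late <- labels[in_era(labels$year, eras$late), ]
      if (nrow(early) == 0L || nrow(late) == 0L) {
        stopf("an era window contains no classified titles")
      }
      pz <- two_proportion_z(sum(early$patient_centric), nrow(early),
                             sum(late$patient_centric), nrow(late))
      lc <- title_length_contrast(early$title, late$title)
      res <- list(
        proportions = pz[c("x_early", "n_early", "x_late", "n_late",
                           "p_early", "p_late", "z", "p_value",
                           "ci_diff")],
        title_length = lc[c("mean_early", "mean_late", "diff", "p_value")]
      )
      jsonlite::write_json(res, file.path(out_dir, "contrast.json"),
                           auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, file.path(out_dir, "contrast.json"))
      note("contrast: %.1f%% -> %.1f%% patient-centric (p = %.3g)",
           100 * pz$p_early, 100 * pz$p_late, pz$p_value)
      res
    })
  }

  if ("report" %in% stages) {
    run_stage("report", {
      acct <- if (!is.null(labels)) {
        per_j <- tapply(rep(1L, nrow(labels)), labels$journal, sum)
        cohort_accounting(data.frame(journal = names(per_j),
                                     n_included = as.integer(per_j)))
      } else {
        cohort_accounting()
      }
      summary <- list(
        cohort = list(per_journal = acct$per_journal, total = acct$total),
        n_records = if (!is.null(records)) nrow(records) else NA,
        significant_terms = lapply(reports, function(r) {
          list(n_screened = nrow(r$results),
               n_significant = sum(r$results$q < r$fdr_threshold))
        }),
        contrast = contrast
      )
      jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA)
      note("report: cohort total %d titles", acct$total)
    })
  }

  manifest <- list(
    tool = "titletrends",
    version = as.character(packageVersion("titletrends")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    stages = stages,
    config_hash = digest_object(config),
    stopwords_version = attr(default_stopwords(), "version"),
    ruleset_version = rule_set()$version,
    file_digests = as.list(tools::md5sum(
      list.files(out_dir, full.names = TRUE,
                 pattern = "\\.(tsv|json|xml)$")
    ))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

combine_records <- function(parts) {
  tibble::tibble(
    pmid = unlist(lapply(parts, `[[`, "pmid")),
    journal = unlist(lapply(parts, `[[`, "journal")),
    year = unlist(lapply(parts, `[[`, "year")),
    title = unlist(lapply(parts, `[[`, "title")),
    pub_types = do.call(c, lapply(parts, `[[`, "pub_types"))
  )
}

# md5 of the canonical JSON serialisation of an R object
digest_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                           force = TRUE)), tmp)
  unname(tools::md5sum(tmp))
}
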