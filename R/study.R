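#' Study-level analysis configuration
#'
#' @param confidence Confidence level for odds-ratio intervals, in
#'   (0.5, 1).
#' @param noteworthiness A [noteworthiness_config()].
#' @param hwe_warn_p Cohorts with HWE p-value below this are flagged as
#'   deviating (the analysis still runs).
#' @param sig_level Associations with p-value at or below this are flagged
#'   significant (inclusive threshold).
#' @return An object of class `study_config`.
#' @export
study_config <- function(confidence = 0.95,
                         noteworthiness = noteworthiness_config(),
                         hwe_warn_p = 0.05,
                         sig_level = 0.05) {
  stopifnot(is.numeric(confidence), length(confidence) == 1L,
            confidence > 0.5, confidence < 1,
            inherits(noteworthiness, "noteworthiness_config"),
            hwe_warn_p > 0, hwe_warn_p < 1,
            sig_level > 0, sig_level < 1)
  structure(list(confidence = confidence, noteworthiness = noteworthiness,
                 hwe_warn_p = hwe_warn_p, sig_level = sig_level),
            class = "study_config")
}

.prior_label <- function(p) {
  format(p, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
}

#' Run the full case-control association study
#'
#' The end-to-end pipeline: for every SNP, both cohorts are tested for
#' Hardy-Weinberg equilibrium, the six genetic model tables are built,
#' each is fitted with [odds_ratio_test()], and every model (significant
#' or not) goes through the FPRP/BFDP noteworthiness screen. The result
#' is a pure function of the input and the configuration; provenance
#' (input checksum, configuration echo, simulation seed when present,
#' package version) is recorded on the returned object.
#'
#' @param input Path to a counts TSV (see [read_counts_table()]), a list
#'   of [cohort_pair()] objects, or a single `cohort_pair`.
#' @param config A [study_config()].
#' @return An object of class `snp_study` with tidy data frames `hwe`,
#'   `association` and `noteworthiness`, the nested per-SNP fits in
#'   `fits`, and `provenance`.
#' @examples
#' study <- run_study(scz_example_counts())
#' study
#' @export
run_study <- function(input, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  checksum <- NA_character_
  source_label <- "in-memory cohort pairs"
  if (is.character(input)) {
    source_label <- input
    checksum <- unname(tools::md5sum(input))
    pairs <- read_counts_table(input)
  } else if (inherits(input, "cohort_pair")) {
    pairs <- list(input)
  } else if (is.list(input) &&
             all(vapply(input, inherits, logical(1L), "cohort_pair"))) {
    pairs <- input
  } else {
    stop("'input' must be a counts TSV path, a cohort_pair, or a list of ",
         "cohort_pair objects", call. = FALSE)
  }
  if (length(pairs) == 0L) stop("no cohort pairs to analyse", call. = FALSE)
  ids <- vapply(pairs, function(p) p$snp$snp_id, character(1L))
  if (anyDuplicated(ids)) {
    stop("duplicate snp_id among cohort pairs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  seeds <- vapply(pairs, function(p) {
    s <- attr(p, "seed")
    if (is.null(s)) NA_integer_ else as.integer(s)
  }, integer(1L))

  hwe_rows <- list()
  assoc_rows <- list()
  nw_rows <- list()
  fits <- stats::setNames(vector("list", length(pairs)), ids)

  for (p in pairs) {
    id <- p$snp$snp_id
    hw <- list(cases = hwe_chi_square(p$cases),
               controls = hwe_chi_square(p$controls))
    for (cohort in names(hw)) {
      h <- hw[[cohort]]
      counts <- p[[cohort]]
      deviates <- h$p.value < config$hwe_warn_p
      if (deviates) {
        message(sprintf("%s [%s]: HWE deviation (p = %.3g < %.3g)",
                        id, cohort, h$p.value, config$hwe_warn_p))
      }
      hwe_rows[[length(hwe_rows) + 1L]] <- data.frame(
        snp_id = id, gene = p$snp$gene, cohort = cohort, n = counts$n,
        freq_ref = h$allele_freq[["ref"]], freq_alt = h$allele_freq[["alt"]],
        chi2 = unname(h$statistic), p_value = h$p.value,
        monomorphic = h$monomorphic, hwe_deviation = deviates,
        stringsAsFactors = FALSE
      )
    }
    tables <- build_all_models(p)
    assoc <- lapply(tables, odds_ratio_test, conf.level = config$confidence)
    nw <- lapply(assoc, evaluate_noteworthiness,
                 config = config$noteworthiness)
    for (m in model_kinds()) {
      fit <- assoc[[m]]
      tab <- tables[[m]]
      assoc_rows[[length(assoc_rows) + 1L]] <- data.frame(
        snp_id = id, gene = p$snp$gene, model = m,
        exposed = tab$exposed_label, baseline = tab$baseline_label,
        a = tab$a, b = tab$b, c = tab$c, d = tab$d,
        or = fit$estimate, ci_low = fit$conf.int[1L],
        ci_high = fit$conf.int[2L], log_or = fit$log_or,
        se_log_or = fit$se_log_or, z = fit$z, p_value = fit$p.value,
        corrected = fit$corrected,
        significant = fit$p.value <= config$sig_level,
        stringsAsFactors = FALSE
      )
      w <- nw[[m]]
      row <- data.frame(snp_id = id, model = m, or = fit$estimate,
                        p_value = w$alpha_observed, direction = w$direction,
                        power = w$power, stringsAsFactors = FALSE)
      for (lab in names(w$fprp)) row[[paste0("fprp_", lab)]] <- w$fprp[[lab]]
      row$abf <- w$abf
      for (lab in names(w$bfdp)) row[[paste0("bfdp_", lab)]] <- w$bfdp[[lab]]
      nw_rows[[length(nw_rows) + 1L]] <- row
    }
    fits[[id]] <- list(pair = p, hwe = hw, tables = tables,
                       association = assoc, noteworthiness = nw)
  }

  structure(
    list(hwe = do.call(rbind, hwe_rows),
         association = do.call(rbind, assoc_rows),
         noteworthiness = do.call(rbind, nw_rows),
         fits = fits,
         config = config,
         provenance = list(
           input = source_label,
           input_md5 = checksum,
           seeds = if (all(is.na(seeds))) NULL else seeds,
           confidence = config$confidence,
           or_threshold = config$noteworthiness$or_threshold,
           fprp_priors = config$noteworthiness$priors,
           bfdp_priors = config$noteworthiness$bfdp_priors,
           package_version = as.character(utils::packageVersion("snpcc")),
           multiple_testing_adjustment = "none"
         )),
    class = "snp_study"
  )
}

#' @export
print.snp_study <- function(x, ...) {
  ids <- names(x$fits)
  cat(sprintf("Case-control SNP association study: %d SNP(s)\n",
              length(ids)))
  cat(sprintf("  input: %s\n", x$provenance$input))
  for (id in ids) {
    hw <- x$hwe[x$hwe$snp_id == id, ]
    as <- x$association[x$association$snp_id == id, ]
    cat(sprintf("\n%s (%s): %d cases / %d controls\n", id, hw$gene[1L],
                hw$n[hw$cohort == "cases"], hw$n[hw$cohort == "controls"]))
    cat(sprintf("  HWE: cases X2 = %.2f (p = %.3f), controls X2 = %.2f (p = %.3f)\n",
                hw$chi2[hw$cohort == "cases"], hw$p_value[hw$cohort == "cases"],
                hw$chi2[hw$cohort == "controls"],
                hw$p_value[hw$cohort == "controls"]))
    for (i in seq_len(nrow(as))) {
      cat(sprintf("  %-12s %-14s OR = %5.2f (%4.2f-%4.2f)  p = %.4f%s\n",
                  as$model[i], paste0(as$exposed[i], " vs. ", as$baseline[i]),
                  as$or[i], as$ci_low[i], as$ci_high[i], as$p_value[i],
                  ifelse(as$significant[i], " *", "")))
    }
  }
  cat("\n* p <=", x$config$sig_level,
      "(no multiple-testing adjustment applied)\n")
  invisible(x)
}

#' @export
summary.snp_study <- function(object, ...) {
  sig <- object$association[object$association$significant, , drop = FALSE]
  structure(list(n_snps = length(object$fits),
                 hwe = object$hwe,
                 significant = sig,
                 noteworthiness = object$noteworthiness,
                 config = object$config),
            class = "summary.snp_study")
}

#' @export
print.summary.snp_study <- function(x, ...) {
  cat(sprintf("snp_study summary: %d SNP(s), %d significant model(s) at p <= %g\n\n",
              x$n_snps, nrow(x$significant), x$config$sig_level))
  cat("Hardy-Weinberg equilibrium:\n")
  hw <- x$hwe
  hw$chi2 <- round(hw$chi2, 2)
  hw$p_value <- round(hw$p_value, 3)
  print(hw[, c("snp_id", "cohort", "n", "chi2", "p_value", "hwe_deviation")],
        row.names = FALSE)
  if (nrow(x$significant)) {
    cat("\nSignificant associations:\n")
    sg <- x$significant
    sg$or <- round(sg$or, 2)
    sg$ci_low <- round(sg$ci_low, 2)
    sg$ci_high <- round(sg$ci_high, 2)
    sg$p_value <- round(sg$p_value, 4)
    print(sg[, c("snp_id", "model", "exposed", "baseline", "or",
                 "ci_low", "ci_high", "p_value")], row.names = FALSE)
  }
  invisible(x)
}

.round_df <- function(df, spec) {
  for (col in names(spec)) {
    hit <- grep(col, names(df))
    for (j in hit) df[[j]] <- round(df[[j]], spec[[col]])
  }
  df
}

#' Write a study report
#'
#' `tsv` emits the three display tables (HWE, association, noteworthiness)
#' in one tab-separated file, each preceded by a `#`-comment section
#' header, with the display rounding policy applied (OR and CI bounds to
#' 2 decimals, p-values to 4, HWE statistics to 2 and HWE p to 3, screen
#' probabilities to 3). `json` serialises the same tables plus provenance
#' at full double precision, so a JSON round trip is lossless.
#'
#' @param study A `snp_study` from [run_study()].
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(study, path, format = c("tsv", "json")) {
  stopifnot(inherits(study, "snp_study"))
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(hwe = study$hwe, association = study$association,
                    noteworthiness = study$noteworthiness,
                    provenance = study$provenance)
    jsonlite::write_json(payload, path, dataframe = "columns",
                         auto_unbox = TRUE, digits = NA, na = "null")
    return(invisible(path))
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  emit <- function(header, df) {
    writeLines(paste0("# ", header), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines("", con)
  }
  hw <- .round_df(study$hwe, list("^freq_" = 4, "^chi2$" = 2,
                                  "^p_value$" = 3))
  emit("Hardy-Weinberg equilibrium", hw)
  as <- .round_df(study$association,
                  list("^or$" = 2, "^ci_" = 2, "^log_or$" = 6,
                       "^se_log_or$" = 6, "^z$" = 4, "^p_value$" = 4))
  emit("Association (odds ratios)", as)
  nw <- .round_df(study$noteworthiness,
                  list("^or$" = 2, "^p_value$" = 4, "^power$" = 3,
                       "^fprp_" = 3, "^abf$" = 4, "^bfdp_" = 3))
  emit("Noteworthiness (FPRP / BFDP)", nw)
  writeLines(c("# No multiple-testing adjustment applied across model tests.",
               paste0("# input_md5: ", study$provenance$input_md5),
               paste0("# package_version: ",
                      study$provenance$package_version)), con)
  invisible(path)
}
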