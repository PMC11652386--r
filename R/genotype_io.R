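#' SNP descriptor for a biallelic variant
#'
#' Bundles the identity and allele orientation of one single-nucleotide
#' polymorphism. The *reference* allele is the baseline of every genetic
#' model downstream; it need not be the major allele (candidate-gene
#' studies often keep the published orientation even when the "variant"
#' allele is the more frequent one, as happens for CYP2E1 rs2070673).
#'
#' @param snp_id Non-empty rsID (or any unique identifier) string.
#' @param gene Gene symbol, or `NA`.
#' @param ref_allele,alt_allele Single characters in `A`, `C`, `G`, `T`
#'   (lowercase accepted, normalised to uppercase); must differ.
#' @param metadata Optional named list of free-form strings (position,
#'   predicted function, MAF, primer sequences, ...). Carried opaquely.
#' @return An object of class `snp_info`.
#' @examples
#' snp_info("rs204993", gene = "NOTCH4", ref_allele = "T", alt_allele = "C")
#' @export
snp_info <- function(snp_id, gene = NA_character_, ref_allele, alt_allele,
                     metadata = list()) {
  if (!is.character(snp_id) || length(snp_id) != 1L || is.na(snp_id) ||
      !nzchar(snp_id)) {
    stop("'snp_id' must be a non-empty string", call. = FALSE)
  }
  ref_allele <- toupper(as.character(ref_allele))
  alt_allele <- toupper(as.character(alt_allele))
  ok <- function(a) length(a) == 1L && !is.na(a) && a %in% c("A", "C", "G", "T")
  if (!ok(ref_allele) || !ok(alt_allele)) {
    stop("alleles must be single characters among A, C, G, T (SNP '",
         snp_id, "')", call. = FALSE)
  }
  if (ref_allele == alt_allele) {
    stop("ref_allele and alt_allele must differ (SNP '", snp_id, "')",
         call. = FALSE)
  }
  structure(
    list(snp_id = snp_id, gene = as.character(gene)[1L],
         ref_allele = ref_allele, alt_allele = alt_allele,
         metadata = metadata),
    class = "snp_info"
  )
}

#' Genotype counts of one cohort at one biallelic SNP
#'
#' The three genotype class counts (reference homozygote, heterozygote,
#' alternate homozygote) for a single cohort. Counts must be non-negative
#' integers with a positive total.
#'
#' @param n_ref_hom,n_het,n_alt_hom Non-negative integer counts.
#' @return An object of class `genotype_counts` with fields `n_ref_hom`,
#'   `n_het`, `n_alt_hom` and the total `n`.
#' @seealso [allele_counts()], [allele_frequency()], [hwe_chi_square()]
#' @examples
#' genotype_counts(60, 102, 48)
#' @export
genotype_counts <- function(n_ref_hom, n_het, n_alt_hom) {
  x <- c(n_ref_hom = n_ref_hom, n_het = n_het, n_alt_hom = n_alt_hom)
  if (length(x) != 3L || anyNA(x) || !is.numeric(x)) {
    stop("genotype counts must be three non-missing numbers", call. = FALSE)
  }
  if (any(x < 0) || any(x != round(x))) {
    stop("genotype counts must be non-negative integers, got (",
         paste(x, collapse = ", "), ")", call. = FALSE)
  }
  n <- sum(x)
  if (n <= 0) {
    stop("total genotype count must be positive", call. = FALSE)
  }
  structure(
    list(n_ref_hom = as.integer(x[[1L]]), n_het = as.integer(x[[2L]]),
         n_alt_hom = as.integer(x[[3L]]), n = as.integer(n)),
    class = "genotype_counts"
  )
}

#' Allele tallies implied by genotype counts
#'
#' Each reference homozygote carries two reference alleles, each
#' heterozygote one of each, so `ref + alt = 2n` always holds.
#'
#' @param counts A [genotype_counts()] object.
#' @return Named integer vector `c(ref = , alt = )`.
#' @export
allele_counts <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  c(ref = 2L * counts$n_ref_hom + counts$n_het,
    alt = 2L * counts$n_alt_hom + counts$n_het)
}

#' Case and control genotype counts for one SNP
#'
#' Pairs the two cohorts of a case-control study at one SNP. Both cohorts
#' share the allele orientation declared in `snp`.
#'
#' @param snp A [snp_info()] object.
#' @param cases,controls [genotype_counts()] objects.
#' @return An object of class `cohort_pair`.
#' @export
cohort_pair <- function(snp, cases, controls) {
  stopifnot(inherits(snp, "snp_info"),
            inherits(cases, "genotype_counts"),
            inherits(controls, "genotype_counts"))
  structure(list(snp = snp, cases = cases, controls = controls),
            class = "cohort_pair")
}

#' @export
print.cohort_pair <- function(x, ...) {
  s <- x$snp
  lab <- c(paste0(s$ref_allele, s$ref_allele),
           paste0(s$ref_allele, s$alt_allele),
           paste0(s$alt_allele, s$alt_allele))
  m <- rbind(cases = unlist(x$cases[1:3]), controls = unlist(x$controls[1:3]))
  colnames(m) <- lab
  cat(sprintf("<cohort_pair> %s (%s), n = %d cases / %d controls\n",
              s$snp_id, ifelse(is.na(s$gene), "-", s$gene),
              x$cases$n, x$controls$n))
  print(m)
  invisible(x)
}

.counts_columns <- c("snp_id", "gene", "ref_allele", "alt_allele",
                     "case_ref_hom", "case_het", "case_alt_hom",
                     "ctrl_ref_hom", "ctrl_het", "ctrl_alt_hom")

#' Read a genotype counts table
#'
#' Parses a tab-separated counts file with one row per SNP: identifiers,
#' allele orientation, and the six genotype counts (three per cohort).
#' Counts are validated as exact non-negative integers; duplicate SNP ids
#' and malformed cells are reported by name.
#'
#' @param path Path to a TSV file with the mandatory header columns
#'   `snp_id`, `gene`, `ref_allele`, `alt_allele`, `case_ref_hom`,
#'   `case_het`, `case_alt_hom`, `ctrl_ref_hom`, `ctrl_het`,
#'   `ctrl_alt_hom`.
#' @return A list of [cohort_pair()] objects, one per row.
#' @examples
#' pairs <- read_counts_table(scz_example_counts())
#' pairs[[2]]
#' @export
read_counts_table <- function(path) {
  if (!file.exists(path)) {
    stop("counts file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE, fileEncoding = "UTF-8")
  missing <- setdiff(.counts_columns, names(df))
  if (length(missing)) {
    stop("counts file is missing column(s): ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop("counts file contains no data rows", call. = FALSE)
  }
  dup <- df$snp_id[duplicated(df$snp_id)]
  if (length(dup)) {
    stop("duplicate snp_id in counts file: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  count_cols <- .counts_columns[5:10]
  parse_count <- function(s, snp, col) {
    if (is.na(s) || !grepl("^[0-9]+$", s)) {
      stop("invalid count '", s, "' in column '", col, "' for SNP '", snp,
           "': counts must be non-negative integers", call. = FALSE)
    }
    as.integer(s)
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    k <- vapply(count_cols, function(col) parse_count(row[[col]],
                                                      row$snp_id, col),
                integer(1L))
    cohort_pair(
      snp = snp_info(row$snp_id, gene = row$gene,
                     ref_allele = row$ref_allele,
                     alt_allele = row$alt_allele),
      cases = genotype_counts(k[[1L]], k[[2L]], k[[3L]]),
      controls = genotype_counts(k[[4L]], k[[5L]], k[[6L]])
    )
  })
}

#' Write cohort pairs back to a counts TSV
#'
#' Inverse of [read_counts_table()]; column order is fixed so that a
#' read/write round trip is the identity on counts.
#'
#' @param pairs List of [cohort_pair()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(pairs, path) {
  if (inherits(pairs, "cohort_pair")) pairs <- list(pairs)
  rows <- lapply(pairs, function(p) {
    data.frame(snp_id = p$snp$snp_id, gene = p$snp$gene,
               ref_allele = p$snp$ref_allele, alt_allele = p$snp$alt_allele,
               case_ref_hom = p$cases$n_ref_hom, case_het = p$cases$n_het,
               case_alt_hom = p$cases$n_alt_hom,
               ctrl_ref_hom = p$controls$n_ref_hom,
               ctrl_het = p$controls$n_het,
               ctrl_alt_hom = p$controls$n_alt_hom,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read per-subject genotype records
#'
#' Long-format subject files carry one row per subject per SNP with columns
#' `subject_id`, `phenotype` (`case` or `control`), `snp_id`, `genotype`
#' (an unordered, unphased allele pair written `X/Y`). Field separator is
#' chosen from the file extension (`.csv` comma, otherwise tab).
#'
#' @param path Path to the subjects file.
#' @return A data frame of subject records (genotypes left as strings;
#'   empty strings become `NA`).
#' @seealso [aggregate_subjects()]
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) {
    stop("subjects file not found: ", path, call. = FALSE)
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE, fileEncoding = "UTF-8")
  need <- c("subject_id", "phenotype", "snp_id", "genotype")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("subjects file is missing column(s): ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  }
  df$genotype[!nzchar(df$genotype)] <- NA_character_
  df
}

#' Aggregate per-subject genotypes into cohort count pairs
#'
#' Tallies unphased genotype records into case/control genotype counts per
#' SNP. Records whose alleles are not among the SNP's declared pair raise a
#' validation error naming the subject; subjects with a missing genotype at
#' a SNP are dropped from that SNP only (with a message giving the count).
#'
#' @param records Data frame as returned by [read_subjects()] (columns
#'   `subject_id`, `phenotype`, `snp_id`, `genotype`).
#' @param snps A list of [snp_info()] objects (or a single one) declaring
#'   every SNP that may appear in `records`.
#' @return A list of [cohort_pair()] objects, one per SNP in `snps` order.
#' @examples
#' snp <- snp_info("rs1", gene = "G1", ref_allele = "G", alt_allele = "A")
#' recs <- data.frame(subject_id = c("s1", "s2", "s3"),
#'                    phenotype = c("case", "case", "control"),
#'                    snp_id = "rs1",
#'                    genotype = c("G/G", "A/G", "A/A"))
#' aggregate_subjects(recs, snp)
#' @export
aggregate_subjects <- function(records, snps) {
  if (inherits(snps, "snp_info")) snps <- list(snps)
  stopifnot(is.data.frame(records),
            all(c("subject_id", "phenotype", "snp_id", "genotype") %in%
                names(records)))
  ids <- vapply(snps, `[[`, character(1L), "snp_id")
  unknown <- setdiff(unique(records$snp_id), ids)
  if (length(unknown)) {
    stop("records refer to undeclared snp_id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad_ph <- setdiff(unique(records$phenotype), c("case", "control"))
  if (length(bad_ph)) {
    stop("phenotype must be 'case' or 'control', got: ",
         paste(bad_ph, collapse = ", "), call. = FALSE)
  }
  lapply(snps, function(snp) {
    rec <- records[records$snp_id == snp$snp_id, , drop = FALSE]
    n_missing <- sum(is.na(rec$genotype))
    if (n_missing > 0L) {
      message(sprintf("%s: dropped %d subject(s) with missing genotype",
                      snp$snp_id, n_missing))
      rec <- rec[!is.na(rec$genotype), , drop = FALSE]
    }
    tally <- function(ph) {
      sub <- rec[rec$phenotype == ph, , drop = FALSE]
      k <- c(0L, 0L, 0L)  # ref-hom, het, alt-hom
      for (j in seq_len(nrow(sub))) {
        alleles <- toupper(strsplit(sub$genotype[j], "/", fixed = TRUE)[[1L]])
        if (length(alleles) != 2L ||
            !all(alleles %in% c(snp$ref_allele, snp$alt_allele))) {
          stop("subject '", sub$subject_id[j], "' has genotype '",
               sub$genotype[j], "' incompatible with SNP '", snp$snp_id,
               "' (", snp$ref_allele, "/", snp$alt_allele, ")",
               call. = FALSE)
        }
        n_alt <- sum(alleles == snp$alt_allele)
        k[n_alt + 1L] <- k[n_alt + 1L] + 1L
      }
      genotype_counts(k[1L], k[2L], k[3L])
    }
    cohort_pair(snp, cases = tally("case"), controls = tally("control"))
  })
}

#' Path to the packaged NOTCH4/CYP2E1 schizophrenia counts table
#'
#' Genotype counts for three SNPs (NOTCH4 rs2071287 and rs204993, CYP2E1
#' rs2070673) from a published Bangladeshi schizophrenia case-control study
#' of 210 patients and 210 matched controls, as a counts TSV in this
#' package's format. These counts drive the examples, [self_test()] and the
#' reproduction scripts.
#'
#' @return Path to the installed TSV file.
#' @examples
#' read_counts_table(scz_example_counts())[[1]]
#' @export
scz_example_counts <- function() {
  system.file("extdata", "scz_notch4_cyp2e1_counts.tsv", package = "snpcc",
              mustWork = TRUE)
}
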