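# shared helpers: the packaged example study and a raw 2x2 constructor

fixture_pairs <- function() {
  read_counts_table(scz_example_counts())
}

fixture_pair <- function(snp_id) {
  pairs <- fixture_pairs()
  pairs[[which(vapply(pairs, function(p) p$snp$snp_id, character(1)) ==
                 snp_id)]]
}

# bare 2x2 table with arbitrary cells, bypassing cohort bookkeeping
mk_table <- function(a, b, c, d, model = "additive2", snp_id = "rsX") {
  structure(list(model = model, snp_id = snp_id,
                 a = a, b = b, c = c, d = d,
                 exposed_label = "exposed", baseline_label = "baseline"),
            class = "model_table")
}

# expand a cohort_pair into per-subject records (inverse of tallying)
expand_to_records <- function(pair) {
  snp <- pair$snp
  geno <- c(paste0(snp$ref_allele, "/", snp$ref_allele),
            paste0(snp$ref_allele, "/", snp$alt_allele),
            paste0(snp$alt_allele, "/", snp$alt_allele))
  one <- function(counts, prefix, phenotype) {
    k <- c(counts$n_ref_hom, counts$n_het, counts$n_alt_hom)
    data.frame(subject_id = sprintf("%s_%04d", prefix, seq_len(sum(k))),
               phenotype = phenotype, snp_id = snp$snp_id,
               genotype = rep(geno, times = k), stringsAsFactors = FALSE)
  }
  rbind(one(pair$cases, "case", "case"),
        one(pair$controls, "ctrl", "control"))
}
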