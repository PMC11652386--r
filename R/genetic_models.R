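#' Canonical genetic model identifiers
#'
#' The six standard 2x2 recodings of a biallelic genotype-by-phenotype
#' table, in the canonical report order:
#' \describe{
#'   \item{additive1}{heterozygote vs reference homozygote (the alternate
#'     homozygotes are dropped from the table)}
#'   \item{additive2}{alternate homozygote vs reference homozygote (the
#'     heterozygotes are dropped)}
#'   \item{dominant}{variant carriers (het + alt-hom) vs reference
#'     homozygote}
#'   \item{recessive}{alternate homozygote vs all other genotypes}
#'   \item{overdominant}{heterozygote vs both homozygote classes}
#'   \item{allelic}{alternate vs reference alleles, on the 2n allele scale}
#' }
#'
#' @return Character vector of the six model names.
#' @export
model_kinds <- function() {
  c("additive1", "additive2", "dominant", "recessive", "overdominant",
    "allelic")
}

.genotype_labels <- function(snp) {
  r <- snp$ref_allele
  a <- snp$alt_allele
  c(ref_hom = paste0(r, r), het = paste0(r, a), alt_hom = paste0(a, a))
}

#' Build the 2x2 contingency table of one genetic model
#'
#' Recodes the case/control genotype counts of a [cohort_pair()] into the
#' 2x2 table of the requested model. The "exposed" category is always the
#' variant-carrying group and the baseline the reference group, so that
#' odds ratios are oriented exactly as the study's declared allele
#' orientation dictates (no automatic re-orientation to the rarer allele).
#' The two additive models drop the unused genotype class entirely, so
#' their column totals are smaller than the cohort sizes; the allelic
#' model counts alleles, so its totals are `2n`.
#'
#' @param pair A [cohort_pair()].
#' @param model One of [model_kinds()].
#' @return An object of class `model_table` with cells `a` (case exposed),
#'   `b` (case baseline), `c` (control exposed), `d` (control baseline)
#'   and the group labels.
#' @examples
#' pairs <- read_counts_table(scz_example_counts())
#' build_model_table(pairs[[2]], "additive2")  # CC vs TT for rs204993
#' @export
build_model_table <- function(pair, model = model_kinds()) {
  stopifnot(inherits(pair, "cohort_pair"))
  model <- match.arg(model)
  lab <- .genotype_labels(pair$snp)
  ca <- pair$cases
  co <- pair$controls
  cells <- switch(
    model,
    additive1 = list(a = ca$n_het, b = ca$n_ref_hom,
                     c = co$n_het, d = co$n_ref_hom,
                     exposed = lab[["het"]], baseline = lab[["ref_hom"]]),
    additive2 = list(a = ca$n_alt_hom, b = ca$n_ref_hom,
                     c = co$n_alt_hom, d = co$n_ref_hom,
                     exposed = lab[["alt_hom"]], baseline = lab[["ref_hom"]]),
    dominant = list(a = ca$n_het + ca$n_alt_hom, b = ca$n_ref_hom,
                    c = co$n_het + co$n_alt_hom, d = co$n_ref_hom,
                    exposed = paste(lab[["het"]], "+", lab[["alt_hom"]]),
                    baseline = lab[["ref_hom"]]),
    recessive = list(a = ca$n_alt_hom, b = ca$n_ref_hom + ca$n_het,
                     c = co$n_alt_hom, d = co$n_ref_hom + co$n_het,
                     exposed = lab[["alt_hom"]],
                     baseline = paste(lab[["ref_hom"]], "+", lab[["het"]])),
    overdominant = list(a = ca$n_het, b = ca$n_ref_hom + ca$n_alt_hom,
                        c = co$n_het, d = co$n_ref_hom + co$n_alt_hom,
                        exposed = lab[["het"]],
                        baseline = paste(lab[["ref_hom"]], "+",
                                         lab[["alt_hom"]])),
    allelic = {
      ac_ca <- allele_counts(ca)
      ac_co <- allele_counts(co)
      list(a = ac_ca[["alt"]], b = ac_ca[["ref"]],
           c = ac_co[["alt"]], d = ac_co[["ref"]],
           exposed = pair$snp$alt_allele, baseline = pair$snp$ref_allele)
    }
  )
  structure(
    list(model = model, snp_id = pair$snp$snp_id,
         a = as.numeric(cells$a), b = as.numeric(cells$b),
         c = as.numeric(cells$c), d = as.numeric(cells$d),
         exposed_label = cells$exposed, baseline_label = cells$baseline),
    class = "model_table"
  )
}

#' @export
print.model_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), nrow = 2,
              dimnames = list(c("cases", "controls"),
                              c(x$exposed_label, x$baseline_label)))
  cat(sprintf("<model_table> %s, %s (%s vs. %s)\n", x$snp_id, x$model,
              x$exposed_label, x$baseline_label))
  print(m)
  invisible(x)
}

#' Build all six genetic model tables
#'
#' @param pair A [cohort_pair()].
#' @return Named list of six `model_table` objects in [model_kinds()]
#'   order.
#' @export
build_all_models <- function(pair) {
  stopifnot(inherits(pair, "cohort_pair"))
  kinds <- model_kinds()
  stats::setNames(lapply(kinds, function(m) build_model_table(pair, m)),
                  kinds)
}
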