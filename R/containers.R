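#' Variant panel: SNP metadata plus a dosage matrix
#'
#' Container for a set of biallelic SNPs with per-sample allele dosages
#' (additive coding, entries in [0, 2], GRCh37-style coordinates). The minor
#' allele frequency stored in \code{snps$maf} is always recomputed from the
#' dosage matrix, so it cannot drift from the genotypes.
#'
#' @param snps data.frame with columns \code{snp}, \code{chrom}, \code{pos}
#'   (1-based), \code{ref}, \code{alt}. Positions must be strictly increasing
#'   within each chromosome.
#' @param dosage numeric matrix, samples x SNPs; column names must equal
#'   \code{snps$snp}. Missing genotypes are allowed before QC
#'   (\code{\link{filter_variants}} removes or imputes them).
#' @return an object of class \code{variant_panel} with elements \code{snps}
#'   (metadata incl. \code{maf}) and \code{dosage}.
#' @export
variant_panel <- function(snps, dosage) {
  stopifnot(is.data.frame(snps),
            all(c("snp", "chrom", "pos", "ref", "alt") %in% names(snps)),
            is.matrix(dosage), ncol(dosage) == nrow(snps))
  if (is.null(colnames(dosage))) colnames(dosage) <- snps$snp
  stopifnot(identical(colnames(dosage), snps$snp))
  if (anyDuplicated(snps$snp)) stop("duplicate SNP ids in panel")
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 2 + 1e-9)
    stop("dosage entries must lie in [0, 2]")
  snps$maf <- panel_maf(dosage)
  structure(list(snps = snps, dosage = dosage), class = "variant_panel")
}

panel_maf <- function(dosage) {
  f <- colMeans(dosage, na.rm = TRUE) / 2
  unname(pmin(f, 1 - f))
}

#' @export
print.variant_panel <- function(x, ...) {
  cat(sprintf("variant_panel: %d samples x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$snps$chrom))))
  cat(sprintf("  MAF range: %.4f - %.4f; missing entries: %d\n",
              min(x$snps$maf), max(x$snps$maf), sum(is.na(x$dosage))))
  invisible(x)
}

#' Subset a variant panel by SNP id or index
#' @param panel a \code{variant_panel}.
#' @param snps character vector of SNP ids or integer indices.
#' @return a \code{variant_panel} restricted to the requested SNPs.
#' @export
panel_subset <- function(panel, snps) {
  idx <- if (is.character(snps)) match(snps, panel$snps$snp) else snps
  if (anyNA(idx)) stop("unknown SNP id(s): ",
                       paste(snps[is.na(idx)], collapse = ", "))
  idx <- sort(idx)
  variant_panel(panel$snps[idx, setdiff(names(panel$snps), "maf"),
                           drop = FALSE],
                panel$dosage[, idx, drop = FALSE])
}

#' Expression matrix with a value tag
#'
#' Features x samples matrix of miRNA abundances tagged with the scale of its
#' values (\code{"counts"}, \code{"rpm"} or \code{"log2cpm"}), plus library
#' sizes and an optional per-row feature table linking rows to mature/precursor
#' miRNA ids.
#'
#' @param values numeric matrix, features x samples, with row and column names.
#' @param tag one of "counts", "rpm", "log2cpm".
#' @param lib_sizes per-sample library sizes; defaults to column sums for raw
#'   counts.
#' @param features optional data.frame aligned with rows (e.g. columns
#'   \code{mature_id}, \code{precursor_id}).
#' @return an \code{expression_matrix} object.
#' @export
expression_matrix <- function(values, tag = c("counts", "rpm", "log2cpm"),
                              lib_sizes = NULL, features = NULL) {
  tag <- match.arg(tag)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (tag == "counts" && any(values < 0)) stop("negative raw counts")
  if (is.null(lib_sizes) && tag == "counts") lib_sizes <- colSums(values)
  if (!is.null(features)) stopifnot(nrow(features) == nrow(values))
  structure(list(values = values, tag = tag, lib_sizes = lib_sizes,
                 features = features), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d features x %d samples\n",
              x$tag, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Ground truth of a simulated dataset
#'
#' Records everything the generator planted so downstream stages can be scored
#' against it: per-feature causal SNPs with their log2-scale effects and
#' variance fractions, trait-level mediation effects, and the per-locus
#' colocalization scenario.
#'
#' @param causal_map data.frame with columns \code{feature}, \code{snp},
#'   \code{beta} (log2-scale allelic effect; may be NA before count simulation
#'   fills in the calibrated value) and \code{var_frac} in [0, 1).
#' @param mediation_map optional data.frame with columns \code{trait},
#'   \code{feature}, \code{effect} (effect of one SD of miRNA on the trait).
#' @param scenario optional named character vector, one of
#'   "shared-causal", "distinct-causal", "null" per locus.
#' @param seed integer seed that (together with the generator arguments)
#'   fully determines the simulated outputs.
#' @return a \code{sim_truth} object.
#' @export
sim_truth <- function(causal_map,
                      mediation_map = NULL,
                      scenario = NULL,
                      seed = NA_integer_) {
  stopifnot(is.data.frame(causal_map),
            all(c("feature", "snp", "var_frac") %in% names(causal_map)))
  if (!"beta" %in% names(causal_map))
    causal_map$beta <- rep(NA_real_, nrow(causal_map))
  if (any(causal_map$var_frac < 0 | causal_map$var_frac >= 1))
    stop("variance fractions must lie in [0, 1)")
  if (!is.null(scenario) &&
      !all(scenario %in% c("shared-causal", "distinct-causal", "null")))
    stop("unknown scenario label")
  structure(list(causal_map = causal_map, mediation_map = mediation_map,
                 scenario = scenario, seed = seed), class = "sim_truth")
}
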