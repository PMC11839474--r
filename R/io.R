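#' Read genotype dosages from a VCF
#'
#' Parses a VCF via \pkg{vcfR}, keeping biallelic SNP records only. Dosages
#' come from the DS FORMAT field when present, otherwise from the GT allele
#' sum. Records are returned sorted by (chrom, pos).
#'
#' @param path path to an (uncompressed or gzipped) VCF.
#' @return a \code{\link{variant_panel}}. Multiallelic/indel records are
#'   skipped with one counted warning; a malformed header is fatal.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  keep[is.na(keep)] <- FALSE
  n_skip <- sum(!keep)
  if (n_skip > 0)
    warning(n_skip, " non-biallelic-SNP record(s) skipped")
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  has_ds <- "DS" %in% unlist(strsplit(v@gt[1, "FORMAT"], ":"))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- matrix(vapply(gsub("\\|", "/", gt), function(g) {
      if (is.na(g) || g %in% c("./.", ".")) return(NA_real_)
      sum(as.numeric(strsplit(g, "/")[[1]]))
    }, numeric(1)), nrow = nrow(gt), dimnames = dimnames(gt))
  }
  ds <- ds[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  id <- fix$ID
  id[is.na(id) | id == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(id) | id == "."]
  ord <- order(fix$CHROM, as.integer(fix$POS))
  snps <- data.frame(snp = id, chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)[ord, ]
  variant_panel(snps, t(ds[ord, , drop = FALSE]))
}

#' Write a variant panel to VCF
#'
#' Emits a minimal VCF 4.2 file with GRCh37-style contig names and both GT
#' (hard call from rounded dosage) and DS fields, so dosages survive a
#' round-trip through \code{\link{read_genotypes}} to 1e-6.
#'
#' @param panel a \code{\link{variant_panel}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(panel, path) {
  stopifnot(inherits(panel, "variant_panel"))
  s <- panel$snps
  samples <- rownames(panel$dosage)
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", unique(s$chrom), ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##FORMAT=<ID=DS,Number=1,Type=Float,",
                  "Description=\"Dosage of the ALT allele\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(s)), function(i) {
    d <- panel$dosage[, i]
    cell <- ifelse(is.na(d), "./.:.",
                   paste0(gt_code[pmin(pmax(round(d), 0), 2) + 1], ":",
                          formatC(d, digits = 6, format = "g")))
    paste(c(s$chrom[i], s$pos[i], s$snp[i], s$ref[i], s$alt[i], ".", "PASS",
            ".", "GT:DS", cell), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Basic variant QC: MAF, Hardy-Weinberg and missingness filters
#'
#' Retains SNPs with MAF >= \code{maf_min}, Hardy-Weinberg chi-squared
#' p >= \code{hwe_p_min} (computed on hard calls, i.e. dosages rounded to
#' 0/1/2), and missingness <= \code{miss_max}. Missing dosages surviving the
#' filter are mean-imputed so downstream matrix operations see a complete
#' panel.
#'
#' @param panel a \code{\link{variant_panel}}.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_p_min minimum HWE p-value (default 1e-8).
#' @param miss_max maximum per-SNP missing fraction (default 0.05).
#' @return the filtered \code{variant_panel}; an empty surviving set is fatal.
#' @export
filter_variants <- function(panel, maf_min = 0.01, hwe_p_min = 1e-8,
                            miss_max = 0.05) {
  stopifnot(inherits(panel, "variant_panel"),
            maf_min >= 0, maf_min <= 0.5, hwe_p_min >= 0, hwe_p_min <= 1,
            miss_max >= 0, miss_max <= 1)
  d <- panel$dosage
  miss <- colMeans(is.na(d))
  maf <- panel_maf(d)
  hwe_p <- apply(d, 2, hwe_pvalue)
  keep <- maf >= maf_min & hwe_p >= hwe_p_min & miss <= miss_max
  if (!any(keep))
    stop("variant QC removed every SNP (maf_min=", maf_min,
         ", hwe_p_min=", hwe_p_min, ", miss_max=", miss_max, ")")
  d <- d[, keep, drop = FALSE]
  for (j in which(colSums(is.na(d)) > 0))
    d[is.na(d[, j]), j] <- mean(d[, j], na.rm = TRUE)
  variant_panel(panel$snps[keep, setdiff(names(panel$snps), "maf"),
                           drop = FALSE], d)
}

#' Hardy-Weinberg chi-squared p-value from dosages
#'
#' Plain 1-df chi-squared goodness-of-fit test on hard-called genotype counts
#' against expectations under the sample allele frequency.
#'
#' @param dosage numeric dosage vector; NAs dropped.
#' @return p-value in (0, 1].
#' @export
hwe_pvalue <- function(dosage) {
  g <- round(dosage[!is.na(dosage)])
  g <- pmin(pmax(g, 0), 2)
  n <- length(g)
  if (n == 0) return(1)
  obs <- tabulate(g + 1L, nbins = 3L)
  p <- (2 * obs[3] + obs[2]) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  x2 <- sum((obs - expd)^2 / expd)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Read BED intervals (0-based half-open) into 1-based inclusive form
#'
#' All package-internal coordinates are 1-based inclusive (the GFF/VCF
#' convention); BED is converted at this boundary.
#'
#' @param path path to a BED file.
#' @return data.frame with chrom, start, end (1-based inclusive).
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Write intervals as BED (0-based half-open)
#' @param intervals data.frame chrom/start/end in 1-based inclusive form.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  stopifnot(all(intervals$start <= intervals$end))
  utils::write.table(
    data.frame(intervals$chrom, intervals$start - 1L, intervals$end),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a miRNA coordinate table
#'
#' Tab-separated with header columns \code{mature_id}, \code{precursor_id},
#' \code{chrom}, \code{start}, \code{end} (1-based inclusive),
#' \code{strand} (+/-), optional \code{arm} (3p/5p) and \code{cluster}.
#' A mature id may map to multiple precursors (each retained); a duplicated
#' (mature_id, precursor_id) pair is rejected.
#'
#' @param path path to the TSV.
#' @return data.frame of class \code{mirna_annotation}.
#' @export
read_mirna_annotation <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mature_id", "precursor_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(a)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  if (any(stats::na.omit(a$start > a$end)))
    stop("coordinate inversion (start > end) in annotation")
  if (!all(a$strand %in% c("+", "-")))
    stop("unknown strand symbol in annotation")
  if (anyDuplicated(a[c("mature_id", "precursor_id")]))
    stop("duplicate (mature_id, precursor_id) entries")
  class(a) <- c("mirna_annotation", "data.frame")
  a
}

#' Read a GWAS / QTL summary-statistics table
#'
#' Tab-separated with header; recognized columns are \code{snp},
#' \code{chrom}, \code{pos}, \code{a1} (effect allele), \code{a2},
#' \code{beta}, \code{se}, \code{z}, \code{p}, \code{n}. A missing z is
#' filled as beta/se; z inconsistent with beta/se beyond 1e-6 is fatal.
#'
#' @param path path to the TSV.
#' @return data.frame with uppercase single-nucleotide alleles.
#' @export
read_summary_stats <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"snp" %in% names(s)) stop("summary stats need a 'snp' column")
  for (al in intersect(c("a1", "a2"), names(s))) {
    s[[al]] <- toupper(s[[al]])
    if (!all(s[[al]] %in% c("A", "C", "G", "T")))
      stop("alleles must be single nucleotides (column ", al, ")")
  }
  if ("se" %in% names(s) && any(stats::na.omit(s$se) <= 0))
    stop("nonpositive standard errors")
  if (!"z" %in% names(s)) {
    if (!all(c("beta", "se") %in% names(s)))
      stop("need either z or beta+se")
    s$z <- s$beta / s$se
  } else if (all(c("beta", "se") %in% names(s))) {
    bad <- abs(s$z - s$beta / s$se) > 1e-6 * pmax(1, abs(s$z))
    if (any(stats::na.omit(bad)))
      stop("z inconsistent with beta/se beyond 1e-6")
  }
  s
}

#' Harmonize effect alleles between two summary-stat tables
#'
#' Matches rows on SNP id when both tables carry ids, otherwise on
#' (chrom, pos). Effects in \code{y} are sign-flipped where its effect allele
#' is \code{x}'s other allele; strand-ambiguous A/T and C/G SNPs and
#' allele-mismatched rows are dropped with a warning.
#'
#' @param x,y summary-stat data.frames with columns snp, a1, a2 and any of
#'   beta/z.
#' @param by "snp" or "position".
#' @return list with the aligned, harmonized tables \code{x} and \code{y}.
#' @export
harmonize_alleles <- function(x, y, by = c("snp", "position")) {
  by <- match.arg(by)
  key_x <- if (by == "snp") x$snp else paste(x$chrom, x$pos)
  key_y <- if (by == "snp") y$snp else paste(y$chrom, y$pos)
  i <- match(key_x, key_y)
  keep <- !is.na(i)
  x <- x[keep, , drop = FALSE]; y <- y[i[keep], , drop = FALSE]
  ambiguous <- (x$a1 == "A" & x$a2 == "T") | (x$a1 == "T" & x$a2 == "A") |
    (x$a1 == "C" & x$a2 == "G") | (x$a1 == "G" & x$a2 == "C")
  same <- x$a1 == y$a1 & x$a2 == y$a2
  flip <- x$a1 == y$a2 & x$a2 == y$a1
  bad <- !(same | flip)
  if (any(ambiguous | bad))
    warning(sum(ambiguous), " strand-ambiguous and ", sum(bad & !ambiguous),
            " allele-mismatched SNP(s) dropped")
  keep <- !ambiguous & !bad
  x <- x[keep, , drop = FALSE]; y <- y[keep, , drop = FALSE]
  fl <- flip[keep]
  for (col in intersect(c("beta", "z"), names(y))) y[[col]][fl] <- -y[[col]][fl]
  if (all(c("a1", "a2") %in% names(y))) {
    tmp <- y$a1[fl]; y$a1[fl] <- y$a2[fl]; y$a2[fl] <- tmp
  }
  list(x = x, y = y)
}

#' Write / read a plain TSV (round-trip helpers for pipeline tables)
#' @param x data.frame.
#' @param path file path.
#' @return \code{path} (writer) or a data.frame (reader).
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)
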