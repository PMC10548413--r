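#' @useDynLib climadapt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx cmdscale cor cov dist ecdf lm median na.omit optimize
#'   p.adjust pchisq plogis pnorm prcomp pt qlogis quantile rbeta rbinom
#'   rnbinom rnorm runif sd setNames var
#' @importFrom utils read.table write.table head tail
NULL

# ---- Containers -------------------------------------------------------------
#
# All genomic coordinates are held 0-based half-open internally; VCF,
# methylation and 1-based feature inputs are converted on read and back on
# write.  Missing genotype dosage is NA.

#' Construct a genotype matrix
#'
#' Holds diploid biallelic genotypes as an individuals x loci dosage matrix
#' (counts of the alternate allele, 0/1/2, NA for missing) together with
#' locus coordinates (stored 0-based).
#'
#' @param dosage integer matrix, samples in rows, loci in columns; values in
#'   \{0, 1, 2, NA\}.
#' @param samples character vector of individual identifiers (row order).
#' @param chrom,pos0 per-locus chromosome name and 0-based position;
#'   positions must be strictly increasing within each chromosome.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, samples, chrom, pos0) {
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != length(samples))
    stop("dosage has ", nrow(dosage), " rows but ", length(samples), " samples")
  if (ncol(dosage) != length(chrom) || length(chrom) != length(pos0))
    stop("locus annotation length does not match dosage columns")
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  if (anyDuplicated(samples)) stop("duplicated sample identifiers")
  for (ch in unique(chrom)) {
    p <- pos0[chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on ", ch)
  }
  rownames(dosage) <- samples
  colnames(dosage) <- paste0(chrom, ":", pos0 + 1L)
  structure(
    list(samples = samples,
         loci = data.frame(chrom = as.character(chrom),
                           pos0 = as.integer(pos0),
                           stringsAsFactors = FALSE),
         dosage = dosage),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$loci), "loci;",
      round(100 * mean(is.na(x$dosage)), 2), "% missing\n")
  invisible(x)
}

#' Construct a population map
#'
#' @param assignments named character vector: names are sample identifiers,
#'   values population codes.
#' @param sites data frame with columns `population`, `longitude`,
#'   `latitude`, `altitude` (one row per population).
#' @return An object of class `population_map`.
#' @export
population_map <- function(assignments, sites) {
  if (anyDuplicated(names(assignments)))
    stop("sample assigned more than once: ",
         paste(unique(names(assignments)[duplicated(names(assignments))]),
               collapse = ", "))
  need <- c("population", "longitude", "latitude", "altitude")
  if (!all(need %in% names(sites)))
    stop("sites must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(sites$population)) stop("duplicated population in sites")
  miss <- setdiff(unique(assignments), sites$population)
  if (length(miss))
    stop("populations without site records: ", paste(miss, collapse = ", "))
  if (any(sites$longitude <= -180 | sites$longitude > 180))
    stop("longitude out of (-180, 180]")
  if (any(sites$latitude < -90 | sites$latitude > 90))
    stop("latitude out of [-90, 90]")
  structure(list(assignments = assignments,
                 sites = as.data.frame(sites)),
            class = "population_map")
}

#' Construct a climate table
#'
#' @param values numeric matrix, sites (populations) in rows, bioclimatic
#'   variables in columns; no missing cells.
#' @param scenario label, e.g. `"current"` or `"RCP8.5_2061-80"`.
#' @export
climate_table <- function(values, scenario = "current") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("climate values need site rownames and variable colnames")
  if (anyDuplicated(colnames(values))) stop("duplicated variable names")
  if (anyNA(values)) stop("climate table has missing cells")
  structure(list(scenario = scenario, values = values,
                 sites = rownames(values), variables = colnames(values)),
            class = "climate_table")
}

#' Construct a methylation table
#'
#' Per-cytosine methylation proportions with read depths. `level` is set NA
#' wherever `depth` is zero.
#'
#' @param level,depth samples x sites matrices: methylation proportion in
#'   \[0, 1\] (NA for missing) and non-negative read depth.
#' @param samples sample identifiers; `sites` a data frame with `chrom`,
#'   `pos0`, `context` (CpG/CHG/CHH).
#' @export
methylation_table <- function(level, depth, samples, sites) {
  level <- as.matrix(level); depth <- as.matrix(depth)
  stopifnot(all(dim(level) == dim(depth)),
            nrow(level) == length(samples), ncol(level) == nrow(sites))
  if (!all(sites$context %in% c("CpG", "CHG", "CHH")))
    stop("context must be CpG, CHG or CHH")
  zero <- depth == 0
  if (any(zero & !is.na(level))) {
    warning("levels at zero-depth cells coerced to missing")
    level[zero] <- NA_real_
  }
  ok <- !is.na(level)
  if (any(level[ok] < 0 | level[ok] > 1)) stop("levels outside [0, 1]")
  site_id <- paste0(sites$chrom, ":", sites$pos0 + 1L)
  dimnames(level) <- dimnames(depth) <- list(samples, site_id)
  structure(list(samples = samples, sites = as.data.frame(sites),
                 level = level, depth = depth),
            class = "methylation_table")
}

#' Construct a feature table
#'
#' Genomic features (e.g. exons) on 0-based half-open coordinates.
#'
#' @param chrom,start0,end0 interval columns (0-based half-open).
#' @param id unique feature identifiers; `annotation` optional text.
#' @export
feature_table <- function(chrom, start0, end0, id, annotation = NA_character_) {
  if (any(start0 >= end0)) stop("feature with start >= end")
  if (anyDuplicated(id)) stop("duplicated feature identifiers")
  structure(data.frame(chrom = as.character(chrom),
                       start0 = as.integer(start0), end0 = as.integer(end0),
                       id = as.character(id), annotation = annotation,
                       stringsAsFactors = FALSE),
            class = c("feature_table", "data.frame"))
}

# ---- Readers ----------------------------------------------------------------

#' Read and filter a VCF into a genotype matrix
#'
#' Retains biallelic SNP records passing, in order: biallelic-SNP check,
#' missing-rate filter, minor-allele-frequency filter, and an observed-
#' heterozygosity filter (heterozygote excess flags likely collapsed
#' paralogs). MAF is computed on non-missing alleles; heterozygosity is the
#' heterozygote fraction among non-missing calls.
#'
#' @param path VCF file (v4.2, GT field; phase ignored).
#' @param min_maf retain loci with minor allele frequency strictly above
#'   this (default 0.01).
#' @param max_missing retain loci with missing-genotype rate strictly below
#'   this (default 0.20).
#' @param max_het retain loci with observed heterozygote fraction at most
#'   this (default 0.5).
#' @return A [genotype_matrix()]; an attribute `filter_log` records counts
#'   removed per rule.
#' @export
read_vcf <- function(path, min_maf = 0.01, max_missing = 0.20, max_het = 0.5) {
  stopifnot(min_maf >= 0, min_maf <= 1, max_missing >= 0, max_missing <= 1,
            max_het >= 0, max_het <= 1)
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_in <- nrow(fix)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  is_snp <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    !grepl(",", alt, fixed = TRUE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n_in)
  # dosage: count of ALT alleles; anything with '.' is missing
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  okgt <- !is.na(gt) & a1 %in% c("0", "1") & a2 %in% c("0", "1")
  dos[okgt] <- (a1 == "1")[okgt] + (a2 == "1")[okgt]
  keep <- is_snp
  n_snp <- sum(keep)
  miss <- rowMeans(is.na(dos))
  keep <- keep & miss < max_missing
  n_miss <- n_snp - sum(keep)
  p_alt <- rowMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  keep2 <- keep & !is.na(maf) & maf > min_maf
  n_maf <- sum(keep) - sum(keep2)
  het <- rowMeans(dos == 1L, na.rm = TRUE)
  keep3 <- keep2 & het <= max_het
  n_het <- sum(keep2) - sum(keep3)
  log <- c(input = n_in, non_biallelic_snp = n_in - n_snp,
           missing_rate = n_miss, maf = n_maf, heterozygosity = n_het,
           retained = sum(keep3))
  if (sum(keep3) == 0L) stop("empty after filtering: no loci passed")
  message("read_vcf: ", paste(names(log), log, sep = "=", collapse = ", "))
  chrom <- fix[keep3, "CHROM"]
  pos0 <- as.integer(fix[keep3, "POS"]) - 1L
  dos <- t(dos[keep3, , drop = FALSE])
  ord <- order(chrom, pos0)
  g <- genotype_matrix(dos[, ord, drop = FALSE], colnames(gt),
                       chrom[ord], pos0[ord])
  attr(g, "filter_log") <- log
  g
}

#' Read a population map and site coordinates
#'
#' @param popmap_path TSV with header columns `sample`, `population`.
#' @param sites_path CSV with header `population, longitude, latitude,
#'   altitude`.
#' @param samples optional sample identifiers to validate against (every
#'   one must appear in the map).
#' @return A [population_map()].
#' @export
read_popmap <- function(popmap_path, sites_path, samples = NULL) {
  pm <- read.table(popmap_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(pm)))
    stop("popmap needs columns sample, population")
  st <- read.table(sites_path, header = TRUE, sep = ",",
                   stringsAsFactors = FALSE)
  for (cc in c("longitude", "latitude", "altitude")) {
    bad <- which(is.na(suppressWarnings(as.numeric(st[[cc]]))))
    if (length(bad))
      stop("malformed ", cc, " in ", sites_path, " line ", bad[1] + 1L)
    st[[cc]] <- as.numeric(st[[cc]])
  }
  if (!is.null(samples)) {
    absent <- setdiff(samples, pm$sample)
    if (length(absent))
      stop("samples missing from population map: ",
           paste(absent, collapse = ", "))
  }
  population_map(setNames(pm$population, pm$sample), st)
}

#' Read a climate table
#'
#' @param path CSV with header `site` followed by bioclimatic variable
#'   columns (default expectation BIO2, BIO4, BIO8, BIO16, BIO19).
#' @param scenario scenario label stored on the table.
#' @export
read_climate <- function(path, scenario = "current") {
  x <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (names(x)[1] != "site") stop("first climate column must be 'site'")
  m <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric climate values in ", path)
  rownames(m) <- x$site
  climate_table(m, scenario = scenario)
}

#' Read per-cytosine methylation calls
#'
#' Long-format TSV `chrom, pos, context, sample, meth_reads, total_reads`
#' (positions 1-based), reshaped to samples x sites level/depth matrices.
#' Levels are methylated / total reads; zero-depth cells are missing.
#' @param path TSV file.
#' @export
read_methylation <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "context", "sample", "meth_reads", "total_reads")
  if (!all(need %in% names(x)))
    stop("methylation TSV needs columns ", paste(need, collapse = ", "))
  site_id <- paste0(x$chrom, ":", x$pos)
  sites <- unique(data.frame(chrom = x$chrom, pos0 = x$pos - 1L,
                             context = x$context, key = site_id,
                             stringsAsFactors = FALSE))
  samples <- unique(x$sample)
  si <- match(site_id, sites$key); pi <- match(x$sample, samples)
  depth <- matrix(0L, length(samples), nrow(sites))
  level <- matrix(NA_real_, length(samples), nrow(sites))
  depth[cbind(pi, si)] <- x$total_reads
  lv <- ifelse(x$total_reads > 0, x$meth_reads / x$total_reads, NA_real_)
  if (any(x$total_reads == 0 & x$meth_reads > 0))
    warning("meth_reads > 0 at zero total depth; level set missing")
  level[cbind(pi, si)] <- lv
  methylation_table(level, depth, samples,
                    sites[, c("chrom", "pos0", "context")])
}

#' Read a feature (exon) table
#'
#' @param path BED (0-based half-open, no header) or a 4-column TSV with
#'   header `chrom, start, end, id` declared 1-based inclusive.
#' @param format `"bed"` or `"tsv1"`.
#' @export
read_features <- function(path, format = c("bed", "tsv1")) {
  format <- match.arg(format)
  if (format == "bed") {
    x <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
    id <- if (ncol(x) >= 4) x[[4]] else paste0("feat", seq_len(nrow(x)))
    feature_table(x[[1]], x[[2]], x[[3]], id)
  } else {
    x <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
    feature_table(x$chrom, x$start - 1L, x$end, x$id)
  }
}

#' Write a result table as TSV
#'
#' Header line, floats at 6 significant digits, row order as given.
#' @param result data frame with a defined column schema.
#' @param path output path.
#' @export
write_table <- function(result, path) {
  stopifnot(is.data.frame(result))
  out <- result
  for (cc in names(out))
    if (is.double(out[[cc]])) out[[cc]] <- signif(out[[cc]], 6)
  tryCatch(
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}
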