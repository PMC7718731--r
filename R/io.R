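# Readers and writers for genotype / phenotype / map / structure files and
# the run configuration. CSV layouts: genotypes have a header row of marker
# ids and one row per individual (first column = individual id); phenotypes
# likewise with trait names; the map has columns marker_id, chrom, pos; the
# structure file is a square matrix with a trait-name header.

#' Load a genotype matrix
#'
#' Reads either a CSV file (header row of marker ids, first column of
#' individual ids, entries 0/1/2) or a PLINK binary triple
#' (\code{.bed}/\code{.bim}/\code{.fam}; pass the path with or without the
#' \code{.bed} extension). PLINK genotypes are mapped to counts of the A1
#' allele (standard additive minor-allele coding). Genotypes are never
#' centered or scaled; the model intercept absorbs the mean.
#'
#' @param path file path (CSV file, or PLINK prefix / .bed path).
#' @param format "csv" or "plink"; guessed from the extension by default.
#' @param map optional data.frame (marker_id, chrom, pos) or path to a map
#'   CSV, used with CSV genotypes; PLINK files carry their own map.
#' @param missing policy for missing genotypes: "error" (default) or
#'   "mode" (fill with the column mode).
#' @return A [GenotypeData-class] object.
#' @export
loadGenotypes <- function(path, format = c("auto", "csv", "plink"),
                          map = NULL, missing = c("error", "mode")) {
  format <- match.arg(format)
  missing <- match.arg(missing)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path) || file.exists(paste0(path, ".bed")))
      "plink" else "csv"
  }
  if (format == "plink") return(readPlink(path, missing = missing))
  if (!file.exists(path)) stop("genotype file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  g <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(g) <- "double"
  if (anyDuplicated(colnames(g)))
    stop("format error: duplicate marker ids in genotype header")
  if (anyNA(g)) {
    if (missing == "error")
      stop("missing genotype values; set missing = \"mode\" to impute with the column mode")
    g <- fillColumnMode(g)
  }
  bad <- !(g %in% c(0, 1, 2))
  if (any(bad))
    stop("coding error: genotype entries must be 0, 1 or 2 (found ",
         paste(unique(g[bad])[1:min(3, sum(bad))], collapse = ", "), ")")
  if (is.character(map)) map <- read.csv(map, stringsAsFactors = FALSE)
  if (!is.null(map)) {
    map$marker_id <- as.character(map$marker_id)
    if (!setequal(map$marker_id, colnames(g)))
      stop("format error: map marker ids do not match genotype header")
    map <- map[match(colnames(g), map$marker_id), , drop = FALSE]
  }
  GenotypeData(g, map = map, individualIds = ids)
}

# Column-mode imputation of NA genotypes.
fillColumnMode <- function(g) {
  for (j in which(colSums(is.na(g)) > 0)) {
    x <- g[, j]
    tab <- table(x[!is.na(x)])
    if (!length(tab)) stop("marker ", j, " entirely missing")
    g[is.na(x), j] <- as.numeric(names(tab)[which.max(tab)])
  }
  g
}

#' Write a genotype CSV
#' @param g a [GenotypeData-class] object.
#' @param path output CSV path.
#' @export
writeGenotypes <- function(g, path) {
  df <- data.frame(id = individualIds(g), check.names = FALSE)
  df <- cbind(df, as.data.frame(genoMatrix(g), check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a phenotype table
#'
#' CSV with a header of trait names and a first column of individual ids.
#' Individuals with any missing trait are dropped (with a message).
#'
#' @param path CSV path.
#' @return A [PhenotypeData-class] object.
#' @export
loadPhenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  y <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(y) <- "double"
  keep <- rowSums(is.na(y)) == 0
  if (!all(keep))
    message("dropping ", sum(!keep), " individual(s) with missing phenotypes")
  PhenotypeData(y[keep, , drop = FALSE], individualIds = ids[keep])
}

#' Write a phenotype CSV
#' @param y a [PhenotypeData-class] object.
#' @param path output CSV path.
#' @export
writePhenotypes <- function(y, path) {
  df <- data.frame(id = individualIds(y), check.names = FALSE)
  df <- cbind(df, as.data.frame(phenoMatrix(y), check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a causal structure matrix
#'
#' Square numeric CSV with a trait-name header (and matching first column
#' of trait names). Entry (k, l) is the structural coefficient of trait l
#' on trait k. Acyclicity of the nonzero support is enforced.
#'
#' @param path CSV path.
#' @return A [CausalStructure-class] object.
#' @export
loadStructure <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  lam <- as.matrix(df[, -1, drop = FALSE])
  rownames(lam) <- as.character(df[[1]])
  storage.mode(lam) <- "double"
  CausalStructure(lam, traitNames = colnames(lam))
}

#' Write a causal structure CSV
#' @param structure a [CausalStructure-class] object.
#' @param path output CSV path.
#' @export
writeStructure <- function(structure, path) {
  lam <- structureMatrix(structure)
  df <- data.frame(trait = traitNames(structure), check.names = FALSE)
  df <- cbind(df, as.data.frame(lam, check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter markers by minor allele frequency
#'
#' The allele frequency of a marker is \code{f = mean(column) / 2} and its
#' minor allele frequency \code{min(f, 1 - f)}. Markers with MAF below
#' \code{minMaf} are removed. Idempotent.
#'
#' @param g a [GenotypeData-class] object.
#' @param minMaf minimum minor allele frequency in [0, 0.5].
#' @return A filtered [GenotypeData-class] object.
#' @export
filterMAF <- function(g, minMaf = 0.05) {
  stopifnot(minMaf >= 0, minMaf <= 0.5)
  f <- colMeans(genoMatrix(g)) / 2
  maf <- pmin(f, 1 - f)
  keep <- maf >= minMaf
  if (!any(keep)) stop("all markers filtered at MAF >= ", minMaf)
  GenotypeData(genoMatrix(g)[, keep, drop = FALSE],
               map = markerMap(g)[keep, , drop = FALSE],
               individualIds = individualIds(g), sort = FALSE)
}

#' Align genotype and phenotype individuals by id
#'
#' Intersects the individual ids of the two objects (keeping the genotype
#' order) and reports how many individuals were dropped from each side.
#'
#' @param g a [GenotypeData-class] object.
#' @param y a [PhenotypeData-class] object.
#' @return list with elements \code{geno} and \code{pheno}, aligned 1:1.
#' @export
alignIndividuals <- function(g, y) {
  common <- intersect(individualIds(g), individualIds(y))
  if (!length(common)) stop("no individuals shared between genotypes and phenotypes")
  dg <- length(individualIds(g)) - length(common)
  dy <- length(individualIds(y)) - length(common)
  if (dg + dy > 0)
    message("alignment dropped ", dg, " genotyped and ", dy,
            " phenotyped individual(s)")
  ig <- match(common, individualIds(g))
  iy <- match(common, individualIds(y))
  list(
    geno = GenotypeData(genoMatrix(g)[ig, , drop = FALSE], map = markerMap(g),
                        individualIds = common, sort = FALSE),
    pheno = PhenotypeData(phenoMatrix(y)[iy, , drop = FALSE],
                          individualIds = common)
  )
}

# ---- PLINK binary (.bed/.bim/.fam) ----------------------------------------
# SNP-major .bed: 3 magic bytes 0x6c 0x1b 0x01, then ceil(n/4) bytes per
# marker, 2 bits per individual (low bits first): 00 = A1/A1 (2 copies of
# A1), 10 = het, 11 = A2/A2 (0 copies), 01 = missing.

readPlink <- function(prefix, missing = "error") {
  prefix <- sub("\\.bed$", "", prefix)
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  if (!all(file.exists(c(bed, bim, fam))))
    stop("PLINK triple incomplete for prefix ", prefix)
  bimdf <- read.table(bim, stringsAsFactors = FALSE)
  famdf <- read.table(fam, stringsAsFactors = FALSE)
  n <- nrow(famdf); p <- nrow(bimdf)
  if (anyDuplicated(bimdf[[2]])) stop("format error: duplicate marker ids in .bim")
  raw <- readBin(bed, what = "raw", n = 3 + ceiling(n / 4) * p)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file: ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  body <- as.integer(raw[-(1:3)])
  bpm <- ceiling(n / 4)
  # decode 4 genotypes per byte; value codes 0,1,2,3 for the 2-bit fields
  codes <- matrix(NA_integer_, nrow = 4 * bpm, ncol = p)
  bytes <- matrix(body, nrow = bpm, ncol = p)
  for (s in 0:3) {
    codes[seq(s + 1, 4 * bpm, by = 4), ] <-
      bitwAnd(bitwShiftR(bytes, 2L * s), 3L)
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> missing
  g <- matrix(NA_real_, n, p)
  g[codes == 0L] <- 2; g[codes == 2L] <- 1; g[codes == 3L] <- 0
  if (anyNA(g)) {
    if (missing == "error")
      stop("missing genotype values in .bed; set missing = \"mode\" to impute")
    g <- fillColumnMode(g)
  }
  map <- data.frame(marker_id = as.character(bimdf[[2]]),
                    chrom = as.character(bimdf[[1]]),
                    pos = as.numeric(bimdf[[4]]), stringsAsFactors = FALSE)
  GenotypeData(g, map = map, individualIds = as.character(famdf[[2]]))
}

#' Write a PLINK .bed/.bim/.fam triple
#'
#' Genotype values are written as counts of the A1 allele in SNP-major
#' order. Reloading with [loadGenotypes()] reproduces the matrix exactly.
#'
#' @param g a [GenotypeData-class] object.
#' @param prefix output path prefix (without extension).
#' @export
writePlink <- function(g, prefix) {
  M <- genoMatrix(g); map <- markerMap(g)
  n <- nrow(M); p <- ncol(M)
  famdf <- data.frame(fid = individualIds(g), iid = individualIds(g),
                      pat = 0, mat = 0, sex = 0, pheno = -9)
  write.table(famdf, paste0(prefix, ".fam"), row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  bimdf <- data.frame(chrom = map$chrom, id = map$marker_id, cm = 0,
                      pos = map$pos, a1 = "A", a2 = "B")
  write.table(bimdf, paste0(prefix, ".bim"), row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  # genotype count -> 2-bit code: 2 -> 00, 1 -> 10, 0 -> 11
  code <- matrix(3L, n, p)
  code[M == 1] <- 2L; code[M == 2] <- 0L
  bpm <- ceiling(n / 4)
  padded <- matrix(0L, 4 * bpm, p)
  padded[seq_len(n), ] <- code
  bytes <- matrix(0L, bpm, p)
  for (s in 0:3)
    bytes <- bytes + bitwShiftL(padded[seq(s + 1, 4 * bpm, by = 4), ,
                                       drop = FALSE], 2L * s)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Load a run configuration
#'
#' YAML key-value file grouping prior settings, chain settings, window size
#' and thresholds. Unspecified keys fall back to package defaults.
#'
#' @param path YAML file path.
#' @return A named list with components \code{chain}, \code{priors},
#'   \code{windows} and any further top-level keys in the file.
#' @export
loadRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    chain = list(n_iter = 20000, burn_in = 5000, thin = 10, seed = 1,
                 output_every = 0),
    priors = list(pi_expect = 0.5, lambda0 = 0, tau2 = 1),
    windows = list(window_size = 100, wppa_threshold = 0.8)
  )
  for (key in names(defaults)) {
    cfg[[key]] <- modifyList(defaults[[key]],
                             if (is.null(cfg[[key]])) list() else cfg[[key]])
  }
  cfg
}
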