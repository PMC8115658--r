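#' Construct a genotype table
#'
#' A genotype table holds an `n` individuals by `q` markers matrix of
#' biallelic genotypes coded as -1 (reference allele) or +1 (alternate
#' allele), together with marker metadata and per-marker minor allele
#' frequencies.
#'
#' @param values Numeric matrix (`n x q`) with entries in `{-1, +1}`.
#'   Row names are individual ids, column names marker ids; defaults are
#'   generated when absent.
#' @param chrom Character vector of chromosome labels, length `q`.
#' @param pos Integer vector of 1-based marker coordinates, length `q`;
#'   must be non-decreasing within each chromosome.
#' @param allow_nonbinary Permit entries other than -1/+1 (e.g. mean-filled
#'   missing calls). Default `FALSE`.
#'
#' @return An object of class `"genotype_table"`: a list with elements
#'   `values`, `chrom`, `pos`, and `maf`, where `maf[k] = min(f, 1 - f)`
#'   and `f` is the fraction of +1 alleles at marker `k`.
#' @export
genotype_table <- function(values, chrom = NULL, pos = NULL,
                           allow_nonbinary = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  q <- ncol(values)
  if (n < 1L || q < 1L) stop("genotype matrix must be non-empty")
  if (is.null(rownames(values))) rownames(values) <- paste0("ind_", seq_len(n))
  if (is.null(colnames(values))) colnames(values) <- paste0("m", seq_len(q))
  if (anyDuplicated(colnames(values)))
    stop("marker ids must be unique")
  if (anyNA(values))
    stop("missing genotypes present; supply a fill policy in load_genotypes()")
  if (!allow_nonbinary && !all(values == -1 | values == 1))
    stop("genotype entries must be -1 or +1 (heterozygous or dosage codes are not supported)")
  if (is.null(chrom)) chrom <- rep("1", q)
  if (is.null(pos)) pos <- seq_len(q)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (length(chrom) != q || length(pos) != q)
    stop("chrom and pos must have one entry per marker")
  for (ch in unique(chrom)) {
    if (is.unsorted(pos[chrom == ch]))
      stop("marker positions must be non-decreasing within chromosome ", ch)
  }
  maf <- compute_maf(values)
  if (any(maf == 0))
    warning(sum(maf == 0), " monomorphic marker(s) (MAF = 0)")
  structure(list(values = values, chrom = chrom, pos = pos, maf = maf),
            class = "genotype_table")
}

compute_maf <- function(values) {
  f <- colMeans(values == 1)
  pmin(f, 1 - f)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("Genotype table:", nrow(x$values), "individuals x", ncol(x$values),
      "markers\n")
  cat("  chromosomes:", paste(unique(x$chrom), collapse = ", "), "\n")
  cat("  MAF range: [", format(min(x$maf), digits = 3), ", ",
      format(max(x$maf), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Load genotypes from a VCF or delimited matrix file
#'
#' Genotypes are mapped to the `{-1, +1}` coding used throughout the
#' package: homozygous reference to -1, homozygous alternate to +1.
#' Markers must be biallelic; heterozygous calls are rejected (the model
#' targets inbred panels and no dominance weighting is defined).
#'
#' @param path Path to the input file.
#' @param format `"auto"` (by extension), `"vcf"`, or `"matrix"`. The
#'   matrix format is a delimited file with a header, an `id` column, and
#'   one column per marker; marker names of the form `chr_pos` are parsed
#'   into chromosome and position.
#' @param fill Policy for missing genotypes: `"none"` (error, default),
#'   `"mean"` (column mean of observed codes; relaxes the strict -1/+1
#'   coding), or `"major"` (majority allele, ties to -1).
#' @param sep Field separator for the matrix format (default tab).
#'
#' @return A [genotype_table()].
#' @export
load_genotypes <- function(path, format = c("auto", "vcf", "matrix"),
                           fill = c("none", "mean", "major"), sep = "\t") {
  format <- match.arg(format)
  fill <- match.arg(fill)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "matrix"
  }
  if (format == "vcf") load_genotypes_vcf(path, fill) else
    load_genotypes_matrix(path, fill, sep)
}

load_genotypes_vcf <- function(path, fill) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = 7L,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    ids <- fix[multi, "ID"]
    ids[is.na(ids) | ids == "."] <-
      paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"])[is.na(ids) | ids == "."]
    stop("multiallelic marker(s): ", paste(utils::head(ids, 5L), collapse = ", "))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  code <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  gt_clean <- gsub("\\|", "/", gt)
  code[gt_clean %in% c("0/0", "0")] <- -1
  code[gt_clean %in% c("1/1", "1")] <- 1
  het <- gt_clean %in% c("0/1", "1/0")
  if (any(het))
    stop("heterozygous genotype calls are not supported (", sum(het),
         " call(s))")
  values <- t(code)  # individuals x markers
  mid <- fix[, "ID"]
  bad <- is.na(mid) | mid == "."
  mid[bad] <- paste0(fix[bad, "CHROM"], "_", fix[bad, "POS"])
  colnames(values) <- mid
  values <- fill_missing(values, fill)
  genotype_table(values, chrom = fix[, "CHROM"],
                 pos = as.integer(fix[, "POS"]),
                 allow_nonbinary = (fill == "mean"))
}

load_genotypes_matrix <- function(path, fill, sep) {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% names(tab)) stop("matrix genotype file needs an 'id' column")
  ids <- as.character(tab$id)
  values <- as.matrix(tab[, setdiff(names(tab), "id"), drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  values <- fill_missing(values, fill)
  mk <- colnames(values)
  parsed <- regmatches(mk, regexec("^(.+)_([0-9]+)$", mk))
  ok <- lengths(parsed) == 3L
  chrom <- rep("1", length(mk)); pos <- seq_along(mk)
  if (all(ok)) {
    chrom <- vapply(parsed, `[`, "", 2L)
    pos <- as.integer(vapply(parsed, `[`, "", 3L))
  }
  genotype_table(values, chrom = chrom, pos = pos,
                 allow_nonbinary = (fill == "mean"))
}

fill_missing <- function(values, fill) {
  if (!anyNA(values)) return(values)
  if (fill == "none")
    stop("missing genotypes present; set fill = \"mean\" or \"major\"")
  for (k in which(colSums(is.na(values)) > 0L)) {
    obs <- values[!is.na(values[, k]), k]
    if (length(obs) == 0L) stop("marker ", colnames(values)[k],
                                " has no observed genotypes")
    repl <- if (fill == "mean") mean(obs) else if (mean(obs) > 0) 1 else -1
    values[is.na(values[, k]), k] <- repl
  }
  values
}

#' Write genotypes to a VCF or delimited matrix file
#'
#' The inverse of [load_genotypes()]: -1 becomes homozygous reference
#' (`0/0`), +1 homozygous alternate (`1/1`).
#'
#' @param G A [genotype_table()].
#' @param path Output path.
#' @param format `"vcf"` or `"matrix"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path, format = c("vcf", "matrix")) {
  format <- match.arg(format)
  if (format == "matrix") {
    tab <- data.frame(id = rownames(G$values), G$values,
                      check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=nbgwas",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  ids <- rownames(G$values)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"), con)
  gt <- ifelse(t(G$values) == 1, "1/1", "0/0")
  body <- paste(G$chrom, G$pos, colnames(G$values), "A", "T", ".", "PASS",
                ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Filter markers by minor allele frequency and adjacent-pair LD
#'
#' Markers with `maf <= maf_min` are dropped first. Surviving markers are
#' then scanned in genomic-position order within each chromosome, and the
#' latter of any adjacent pair with squared Pearson correlation
#' `>= ld_r2_max` is dropped (adjacent-only pruning, not windowed): each
#' candidate is compared against the most recent marker that was kept.
#'
#' @param G A [genotype_table()].
#' @param maf_min MAF threshold in `[0, 0.5)`; markers at or below it are
#'   removed. Use 0 to drop only monomorphic markers.
#' @param ld_r2_max Adjacent-pair squared-correlation threshold in
#'   `(0, 1]`; `NULL` disables LD pruning.
#' @return A filtered [genotype_table()].
#' @export
filter_markers <- function(G, maf_min = 0.05, ld_r2_max = 0.8) {
  stopifnot(inherits(G, "genotype_table"))
  if (maf_min < 0 || maf_min >= 0.5) stop("maf_min must be in [0, 0.5)")
  keep <- G$maf > maf_min
  if (!is.null(ld_r2_max)) {
    if (ld_r2_max <= 0 || ld_r2_max > 1) stop("ld_r2_max must be in (0, 1]")
    for (ch in unique(G$chrom)) {
      idx <- which(keep & G$chrom == ch)
      idx <- idx[order(G$pos[idx])]
      if (length(idx) < 2L) next
      last <- idx[1L]
      for (k in idx[-1L]) {
        r <- suppressWarnings(stats::cor(G$values[, last], G$values[, k]))
        if (!is.na(r) && r * r >= ld_r2_max) keep[k] <- FALSE else last <- k
      }
    }
  }
  if (!any(keep))
    stop("no markers survive maf_min = ", maf_min,
         ", ld_r2_max = ", if (is.null(ld_r2_max)) "NULL" else ld_r2_max)
  subset_markers(G, which(keep))
}

subset_markers <- function(G, idx) {
  out <- list(values = G$values[, idx, drop = FALSE],
              chrom = G$chrom[idx], pos = G$pos[idx], maf = G$maf[idx])
  class(out) <- "genotype_table"
  out
}

#' Load a phenotype/covariate table or a spatial map
#'
#' Reads a delimited file with a header and an `id` column, checks the ids
#' against a genotype table, and reorders rows to the genotype individual
#' order.
#'
#' @param path Path to a delimited file.
#' @param role `"phenotype"` or `"map"`. A map must have numeric `x` and
#'   `y` columns; a phenotype table's first non-id column is the phenotype,
#'   remaining columns are covariates.
#' @param geno A [genotype_table()] defining the individual order.
#' @param sep Field separator (default tab).
#' @param allow_duplicates For maps: allow coincident coordinates
#'   (default `FALSE`).
#' @return For `role = "phenotype"` a `data.frame` (id, phenotype,
#'   covariates) in genotype order; for `role = "map"` a [spatial_map()].
#' @export
load_table <- function(path, role = c("phenotype", "map"), geno,
                       sep = "\t", allow_duplicates = FALSE) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% names(tab)) stop(role, " file needs an 'id' column")
  ids <- rownames(geno$values)
  miss <- setdiff(ids, as.character(tab$id))
  if (length(miss) > 0L)
    stop("individuals missing from ", role, " table: ",
         paste(utils::head(miss, 10L), collapse = ", "))
  tab <- tab[match(ids, as.character(tab$id)), , drop = FALSE]
  rownames(tab) <- NULL
  if (role == "map") {
    if (!all(c("x", "y") %in% names(tab)))
      stop("map file needs 'x' and 'y' columns")
    return(spatial_map(tab$id, tab$x, tab$y,
                       allow_duplicates = allow_duplicates))
  }
  tab
}

#' Construct a spatial map of individual positions
#'
#' @param id Individual identifiers.
#' @param x,y Planar coordinates.
#' @param lattice Optional list describing a regular lattice:
#'   `list(rows, cols, checkered)` with unit cell spacing. Required by
#'   [lattice_thresholds()].
#' @param allow_duplicates Allow coincident positions (default `FALSE`).
#' @return A `data.frame` of class `"spatial_map"` with columns `id`,
#'   `x`, `y` and a `"lattice"` attribute.
#' @export
spatial_map <- function(id, x, y, lattice = NULL, allow_duplicates = FALSE) {
  m <- data.frame(id = as.character(id), x = as.numeric(x),
                  y = as.numeric(y), stringsAsFactors = FALSE)
  if (!allow_duplicates && anyDuplicated(m[, c("x", "y")]))
    stop("duplicate coordinates in spatial map (set allow_duplicates = TRUE to permit)")
  attr(m, "lattice") <- lattice
  class(m) <- c("spatial_map", "data.frame")
  m
}
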