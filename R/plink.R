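#' Genotype matrix container
#'
#' Holds coded allele counts for a set of animals at biallelic SNPs, together
#' with the PED pedigree columns and the MAP SNP records. Calls count copies
#' of the "1"-coded reference allele, so values lie in `{0, 1, 2, NA}`.
#'
#' @param calls integer matrix, animals in rows (rownames = individual ids),
#'   SNPs in columns (colnames = SNP ids); `NA` marks a missing call.
#' @param fam data frame with the six leading PED columns
#'   (`fid`, `iid`, `pat`, `mat`, `sex`, `pheno`), one row per animal.
#' @param map data frame with columns `chr`, `snp`, `cm`, `bp`, one row per
#'   SNP in column order of `calls`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, fam, map) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(fam))
    stop("calls has ", nrow(calls), " rows but fam describes ", nrow(fam),
         " animals")
  if (ncol(calls) != nrow(map))
    stop("calls has ", ncol(calls), " columns but map describes ", nrow(map),
         " SNPs")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype calls must be 0, 1, 2 or NA")
  key <- paste(fam$fid, fam$iid, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (family id, individual id) pair: ",
         paste(fam$iid[duplicated(key)], collapse = ", "))
  if (anyDuplicated(fam$iid))
    stop("individual ids must be unique across families")
  rownames(calls) <- as.character(fam$iid)
  colnames(calls) <- as.character(map$snp)
  structure(list(calls = calls, fam = fam, map = map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "animals x", ncol(x$calls), "SNPs;",
      sum(is.na(x$calls)), "missing calls\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

.split_ws <- function(lines) strsplit(trimws(lines), "[ \t]+")

#' Read PLINK text genotypes (PED/MAP, recode12 coding)
#'
#' Parses the two-file text dialect in which each PED row carries six
#' pedigree fields followed by two allele codes per SNP, alleles coded
#' `1`/`2` and `0` for missing (the `--recode12` convention). The genotype
#' value is the number of "1" alleles in the pair; a pair containing any `0`
#' is a missing call.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file (4 whitespace-separated fields:
#'   chromosome, SNP id, genetic distance, bp position).
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  if (length(map_lines)) {
    toks <- .split_ws(map_lines)
    nf <- lengths(toks)
    if (any(nf != 4L))
      stop("MAP line ", which(nf != 4L)[1L], ": expected 4 fields, found ",
           nf[nf != 4L][1L])
    mm <- do.call(rbind, toks)
    map <- data.frame(chr = mm[, 1L], snp = mm[, 2L],
                      cm = as.numeric(mm[, 3L]), bp = as.numeric(mm[, 4L]),
                      stringsAsFactors = FALSE)
  } else {
    map <- data.frame(chr = character(), snp = character(),
                      cm = numeric(), bp = numeric())
  }
  n_snp <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  if (!length(ped_lines)) stop("PED file ", ped_path, " contains no rows")
  toks <- .split_ws(ped_lines)
  nf <- lengths(toks)
  want <- 6L + 2L * n_snp
  if (any(nf != want))
    stop("PED line ", which(nf != want)[1L], ": expected ", want,
         " fields (6 + 2 x ", n_snp, " SNPs), found ", nf[nf != want][1L])
  n <- length(toks)
  fam <- data.frame(
    fid = vapply(toks, `[[`, "", 1L), iid = vapply(toks, `[[`, "", 2L),
    pat = vapply(toks, `[[`, "", 3L), mat = vapply(toks, `[[`, "", 4L),
    sex = vapply(toks, `[[`, "", 5L), pheno = vapply(toks, `[[`, "", 6L),
    stringsAsFactors = FALSE)
  if (n_snp > 0L) {
    al <- matrix(0L, n, 2L * n_snp)
    for (i in seq_len(n)) {
      v <- suppressWarnings(as.integer(toks[[i]][-(1:6)]))
      if (anyNA(v) || any(v < 0L | v > 2L))
        stop("PED line ", i, ": allele codes must be 0, 1 or 2 (recode12)")
      al[i, ] <- v
    }
    a1 <- al[, seq(1L, 2L * n_snp, by = 2L), drop = FALSE]
    a2 <- al[, seq(2L, 2L * n_snp, by = 2L), drop = FALSE]
    calls <- (a1 == 1L) + (a2 == 1L)
    calls[a1 == 0L | a2 == 0L] <- NA_integer_
  } else {
    calls <- matrix(integer(), n, 0L)
  }
  genotype_matrix(calls, fam, map)
}

#' Write PLINK text genotypes (PED/MAP, recode12 coding)
#'
#' Emits exactly the dialect that [read_plink()] consumes: call 2 becomes
#' `1 1`, call 1 becomes `1 2`, call 0 becomes `2 2`, and a missing call
#' becomes `0 0`.
#'
#' @param g a [genotype_matrix()].
#' @param ped_path,map_path output paths.
#' @return Invisibly, the PED path.
#' @export
write_plink <- function(g, ped_path, map_path) {
  stopifnot(inherits(g, "genotype_matrix"))
  map <- g$map
  writeLines(if (nrow(map)) paste(map$chr, map$snp, map$cm, map$bp, sep = "\t")
             else character(), map_path)
  codes <- c("2 2", "1 2", "1 1")
  calls <- g$calls
  lead <- paste(g$fam$fid, g$fam$iid, g$fam$pat, g$fam$mat, g$fam$sex,
                g$fam$pheno)
  if (ncol(calls)) {
    txt <- matrix(codes[calls + 1L], nrow(calls), ncol(calls))
    txt[is.na(calls)] <- "0 0"
    body <- apply(txt, 1L, paste, collapse = " ")
    writeLines(paste(lead, body), ped_path)
  } else {
    writeLines(lead, ped_path)
  }
  invisible(ped_path)
}

#' Apply genotype quality control
#'
#' Three-stage filter mirroring the usual single-pass PLINK invocation:
#' first individuals whose fraction of missing calls exceeds `mind` are
#' removed, then (on the retained individuals) SNPs with missing fraction
#' above `geno`, then SNPs whose minor allele frequency falls strictly below
#' `maf`. Statistics for each stage are recomputed on what survived the
#' previous stage; a SNP with MAF exactly equal to `maf` is kept.
#'
#' @param g a [genotype_matrix()].
#' @param mind,geno,maf thresholds in `[0, 1)`; defaults 0.05 each.
#' @return A list with elements `genotypes` (the filtered
#'   [genotype_matrix()]) and `report` (a `qc_report`).
#' @export
apply_qc <- function(g, mind = 0.05, geno = 0.05, maf = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  for (th in c(mind, geno, maf))
    if (!is.numeric(th) || th < 0 || th >= 1)
      stop("QC thresholds must lie in [0, 1)")
  calls <- g$calls
  n_ind0 <- nrow(calls); n_snp0 <- ncol(calls)

  ind_miss <- if (n_snp0) rowMeans(is.na(calls)) else rep(0, n_ind0)
  keep_ind <- ind_miss <= mind
  if (!any(keep_ind))
    stop("QC removed every individual (mind = ", mind, ")")
  calls <- calls[keep_ind, , drop = FALSE]

  snp_miss <- if (nrow(calls)) colMeans(is.na(calls)) else numeric(n_snp0)
  keep_geno <- snp_miss <= geno
  calls <- calls[, keep_geno, drop = FALSE]

  nn <- colSums(!is.na(calls))
  p <- colSums(calls, na.rm = TRUE) / (2 * pmax(nn, 1L))
  snp_maf <- pmin(p, 1 - p)
  keep_maf <- snp_maf >= maf & nn > 0L
  calls <- calls[, keep_maf, drop = FALSE]

  out <- genotype_matrix(calls,
                         g$fam[keep_ind, , drop = FALSE],
                         g$map[keep_geno, , drop = FALSE][keep_maf, ,
                                                          drop = FALSE])
  report <- structure(list(
    n_input_individuals = n_ind0,
    n_input_snps = n_snp0,
    individuals_removed = sum(!keep_ind),
    snps_removed_missingness = sum(!keep_geno),
    snps_removed_maf = sum(!keep_maf),
    snps_pass = ncol(calls),
    thresholds = c(mind = mind, geno = geno, maf = maf)
  ), class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  th <- x$thresholds
  cat("QC (mind ", th["mind"], ", geno ", th["geno"], ", maf ", th["maf"],
      "):\n", sep = "")
  cat("  individuals removed (low call rate): ", x$individuals_removed, "\n",
      "  SNPs removed (missingness):          ", x$snps_removed_missingness,
      "\n",
      "  SNPs removed (MAF):                  ", x$snps_removed_maf, "\n",
      "  SNPs passing:                        ", x$snps_pass, "\n", sep = "")
  invisible(x)
}

#' Serialize a QC report as TSV
#' @param report a `qc_report` from [apply_qc()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(
    metric = c("input_individuals", "input_snps", "individuals_removed",
               "snps_removed_missingness", "snps_removed_maf", "snps_pass",
               "mind", "geno", "maf"),
    value = c(report$n_input_individuals, report$n_input_snps,
              report$individuals_removed, report$snps_removed_missingness,
              report$snps_removed_maf, report$snps_pass,
              report$thresholds))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
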