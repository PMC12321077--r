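## Tabular input/output and allele harmonization.
##
## All readers validate rows against the variant-record invariants and drop
## invalid rows with a logged count, so downstream math never sees an
## inconsistent record. Rejection accounting holds for every reader:
## rows_in == rows_kept + rows_rejected.

.BASES <- c("A", "C", "G", "T")

.sumstats_cols <- c("snp", "chr", "pos", "ea", "oa", "eaf",
                    "beta", "se", "pval", "n")

.actions <- c("agonist", "antagonist", "partial_agonist", "inverse_agonist",
              "positive_modulator", "inhibitor", "unknown")

#' Read GWAS or eQTL summary statistics
#'
#' Reads a tab-delimited summary-statistics table with header columns
#' `snp, chr, pos, ea, oa, eaf, beta, se, pval, n` (plus `gene, tissue`
#' when `eqtl = TRUE`). Every row is validated: effect and other allele
#' must be distinct single bases, `se > 0`, `pval` in (0, 1], `n > 0`,
#' `pos >= 1`, and `eaf` in [0, 1] when present (missing `eaf` is
#' tolerated -- neither the Wald ratio nor the ABF needs it when `se` is
#' available). Invalid rows are dropped and their count logged via
#' [message()] and attached as the `"n_rejected"` attribute.
#'
#' @param path Path to a TSV file with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names (names) to the file's column names (values), e.g.
#'   `c(snp = "rsid", beta = "b")`.
#' @param eqtl Logical; if `TRUE`, `gene` and `tissue` columns are also
#'   required.
#' @return A `data.frame` of validated records with canonical column
#'   names, with attributes `n_rejected` (count of dropped rows) and
#'   `n_read` (rows in the file).
#' @export
read_sumstats <- function(path, schema = NULL, eqtl = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  required <- .sumstats_cols
  if (eqtl) required <- c(required, "gene", "tissue")
  wanted <- required
  if (!is.null(schema)) {
    wanted <- ifelse(required %in% names(schema), schema[required], required)
  }
  missing_cols <- wanted[!wanted %in% names(raw)]
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- raw[, wanted, drop = FALSE]
  names(x) <- required

  n_read <- nrow(x)
  num <- function(v) suppressWarnings(as.numeric(v))
  x$pos <- num(x$pos); x$eaf <- num(x$eaf); x$beta <- num(x$beta)
  x$se <- num(x$se); x$pval <- num(x$pval); x$n <- num(x$n)
  x$ea <- toupper(x$ea); x$oa <- toupper(x$oa)

  ok <- !is.na(x$snp) & nzchar(x$snp) &
    x$ea %in% .BASES & x$oa %in% .BASES & x$ea != x$oa &
    !is.na(x$pos) & x$pos >= 1 &
    !is.na(x$beta) & is.finite(x$beta) &
    !is.na(x$se) & x$se > 0 &
    !is.na(x$pval) & x$pval > 0 & x$pval <= 1 &
    !is.na(x$n) & x$n > 0 &
    (is.na(x$eaf) | (x$eaf >= 0 & x$eaf <= 1))
  if (eqtl) ok <- ok & nzchar(x$gene) & nzchar(x$tissue)

  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    message("read_sumstats: rejected ", n_rejected, " of ", n_read,
            " row(s) in ", basename(path))
  }
  out <- x[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  attr(out, "n_read") <- n_read
  out
}

#' Write summary statistics as TSV
#'
#' Writes with full double precision (15 significant digits) so that a
#' write-then-read round trip preserves every field.
#'
#' @param x A summary-statistics `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  write_tsv(x, path)
}

## Internal: deterministic full-precision TSV writer used by all stages.
write_tsv <- function(x, path) {
  df <- as.data.frame(x)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.15g", df[[j]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.is_palindromic <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

## Internal vectorized allele comparison:
## "same"        alleles match in the same orientation
## "flip"        alleles match with effect/other swapped (flip outcome beta)
## "palindromic" strand-ambiguous A/T or C/G pair, rejected
## "mismatch"    allele sets differ as unordered pairs, rejected
harmonize_status <- function(ea_x, oa_x, ea_y, oa_y) {
  status <- rep("mismatch", length(ea_x))
  pal <- .is_palindromic(ea_x, oa_x)
  same <- ea_x == ea_y & oa_x == oa_y
  flip <- ea_x == oa_y & oa_x == ea_y
  status[same] <- "same"
  status[flip] <- "flip"
  status[pal] <- "palindromic"
  status
}

#' Harmonize an outcome record to an exposure record
#'
#' Aligns the outcome's effect allele to the exposure's. If the outcome's
#' alleles are swapped relative to the exposure, the outcome beta sign is
#' flipped (and `eaf` complemented when present). Palindromic (A/T, C/G)
#' variants are rejected as strand-ambiguous: with a single instrument a
#' mis-oriented allele flips the whole causal estimate, so frequency-based
#' resolution is not attempted. Harmonization is an involution: applying
#' it to an already-harmonized pair changes nothing.
#'
#' @param exposure,outcome Single records (one-row `data.frame` or named
#'   list) with at least `snp, ea, oa, beta` (`eaf` optional).
#' @return A list with `ok` (logical), `reason` (`NA`, `"palindromic"`,
#'   `"allele_mismatch"` or `"snp_mismatch"`), `flipped` (logical),
#'   `exposure` and the (possibly sign-corrected) `outcome`.
#' @export
harmonize <- function(exposure, outcome) {
  exposure <- as.list(exposure)
  outcome <- as.list(outcome)
  rej <- function(reason) list(ok = FALSE, reason = reason, flipped = NA,
                               exposure = exposure, outcome = outcome)
  if (!identical(as.character(exposure$snp), as.character(outcome$snp))) {
    return(rej("snp_mismatch"))
  }
  status <- harmonize_status(exposure$ea, exposure$oa, outcome$ea, outcome$oa)
  if (status == "palindromic") return(rej("palindromic"))
  if (status == "mismatch") return(rej("allele_mismatch"))
  flipped <- status == "flip"
  if (flipped) {
    tmp <- outcome$ea; outcome$ea <- outcome$oa; outcome$oa <- tmp
    outcome$beta <- -outcome$beta
    if (!is.null(outcome$eaf) && !is.na(outcome$eaf)) {
      outcome$eaf <- 1 - outcome$eaf
    }
  }
  list(ok = TRUE, reason = NA_character_, flipped = flipped,
       exposure = exposure, outcome = outcome)
}

#' Read a drug-receptor binding-affinity table
#'
#' CSV with header columns `drug, receptor, ki_nM, action, source`.
#' Duplicated (drug, receptor) rows are expected and retained: they are
#' independent laboratory measurements that the trimmed mean later
#' summarizes. A blank `ki_nM` is kept as a missing measurement (it marks
#' a pair known to bind but unmeasured, which drives default-pKi
#' imputation); a negative or zero `ki_nM` is a row-level rejection.
#' Unrecognized `action` labels are coerced to `"unknown"`.
#'
#' @param path CSV path.
#' @return `data.frame` with columns `drug, receptor, ki_nM, action,
#'   source` and attributes `n_rejected`, `n_read`.
#' @export
read_affinity_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("drug", "receptor", "ki_nM", "action")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"source" %in% names(raw)) raw$source <- NA_character_
  x <- raw[, c("drug", "receptor", "ki_nM", "action", "source")]
  n_read <- nrow(x)
  blank <- is.na(x$ki_nM) | !nzchar(trimws(x$ki_nM))
  ki <- suppressWarnings(as.numeric(x$ki_nM))
  ki[blank] <- NA_real_
  ## blank = legitimately missing; parsed but non-positive = rejected
  ok <- nzchar(x$drug) & nzchar(x$receptor) &
    (blank | (!is.na(ki) & ki > 0))
  x$ki_nM <- ki
  bad_action <- !x$action %in% .actions
  if (any(bad_action & ok)) {
    message("read_affinity_table: coerced ", sum(bad_action & ok),
            " unrecognized action label(s) to 'unknown'")
    x$action[bad_action] <- "unknown"
  }
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    message("read_affinity_table: rejected ", n_rejected, " of ", n_read,
            " row(s)")
  }
  out <- x[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  attr(out, "n_read") <- n_read
  out
}

#' Read the side-effect to phenotype map
#'
#' CSV with columns `side_effect, phenotype_id, brain_relevant`. One
#' side-effect may map to several GWAS phenotypes (the screen later keeps
#' a single best result per side-effect/receptor pair); each
#' (side_effect, phenotype_id) pair must be unique.
#'
#' @param path CSV path.
#' @return `data.frame` with `brain_relevant` as logical.
#' @export
read_side_effect_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("side_effect", "phenotype_id", "brain_relevant")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- x[, need]
  x$brain_relevant <- as.logical(x$brain_relevant)
  if (any(is.na(x$brain_relevant))) {
    stop("brain_relevant must be TRUE/FALSE for every row", call. = FALSE)
  }
  key <- paste(x$side_effect, x$phenotype_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (side_effect, phenotype_id) pair(s) in map", call. = FALSE)
  }
  x
}

#' Read the drug dose-equivalents table
#'
#' CSV with columns `drug, dose_equivalent`; dose equivalents are
#' dimensionless, centered around 1, and must be strictly positive.
#'
#' @param path CSV path.
#' @return `data.frame(drug, dose_equivalent)`.
#' @export
read_dose_equivalents <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "dose_equivalent")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x$dose_equivalent <- as.numeric(x$dose_equivalent)
  if (any(is.na(x$dose_equivalent) | x$dose_equivalent <= 0)) {
    stop("dose_equivalent must be > 0 for every drug", call. = FALSE)
  }
  x[, need]
}

#' Read the gene annotation table
#'
#' TSV with columns `gene, chrom, start, end` (1-based, inclusive); used
#' to define each gene's cis window for instrument selection and
#' colocalization.
#'
#' @param path TSV path.
#' @return `data.frame(gene, chrom, start, end)`.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- read_tsv(path)
  need <- c("gene", "chrom", "start", "end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  if (any(is.na(x$start) | is.na(x$end) | x$start < 1 | x$end < x$start)) {
    stop("gene intervals must satisfy 1 <= start <= end", call. = FALSE)
  }
  x[, need]
}
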