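#' Construct a summarized-data object for Mendelian randomization
#'
#' Bundles per-variant genetic association estimates with the exposure
#' (risk factor) and with the outcome into the container used by all
#' estimation functions. The exposure association for variant k is
#' \eqn{X_k} with standard error \eqn{\sigma_{Xk}}; the outcome
#' association is \eqn{Y_k} with standard error \eqn{\sigma_{Yk}}.
#' Associations are assumed to be per-allele effects reported for a
#' common (harmonized) effect allele in both sources; use
#' [read_mr_summary()] to build the object from raw files with
#' harmonization.
#'
#' @param snp character vector of variant identifiers (e.g. rsIDs).
#' @param beta_exposure,se_exposure numeric vectors: per-allele
#'   association estimates with the exposure and their standard errors.
#' @param beta_outcome,se_outcome numeric vectors: per-allele
#'   association estimates with the outcome and their standard errors.
#' @param effect_allele,other_allele optional character vectors of
#'   alleles (single letters or symbolic labels).
#' @param eaf optional numeric vector of effect allele frequencies in
#'   (0, 1).
#' @param pval_exposure,pval_outcome optional p-values; when supplied
#'   they are checked for consistency with beta/se under a two-sided
#'   normal test (a warning, not an error, on >10\% relative
#'   disagreement).
#' @return An object of class `mr_summary_data`: a data frame with one
#'   row per variant and attribute `K` (the number of variants).
#' @examples
#' d <- mr_summary_data(
#'   snp = c("rs1", "rs2"),
#'   beta_exposure = c(0.5, 0.4), se_exposure = c(0.05, 0.05),
#'   beta_outcome = c(0.10, 0.09), se_outcome = c(0.02, 0.02))
#' mr_ivw(d)
#' @export
mr_summary_data <- function(snp, beta_exposure, se_exposure,
                            beta_outcome, se_outcome,
                            effect_allele = NULL, other_allele = NULL,
                            eaf = NULL,
                            pval_exposure = NULL, pval_outcome = NULL) {
  K <- length(snp)
  if (K < 1L) stop("at least one variant is required (K >= 1)")
  snp <- as.character(snp)
  if (anyDuplicated(snp)) stop("duplicated variant identifiers: ",
                               paste(unique(snp[duplicated(snp)]), collapse = ", "))
  num <- list(beta_exposure = beta_exposure, se_exposure = se_exposure,
              beta_outcome = beta_outcome, se_outcome = se_outcome)
  for (nm in names(num)) {
    if (length(num[[nm]]) != K || !is.numeric(num[[nm]]) || anyNA(num[[nm]]))
      stop("'", nm, "' must be numeric of length ", K, " without NA")
  }
  if (any(se_exposure <= 0) || any(se_outcome <= 0))
    stop("all standard errors must be strictly positive")
  if (!is.null(eaf) && any(eaf <= 0 | eaf >= 1, na.rm = TRUE))
    stop("'eaf' must lie in (0, 1)")
  .check_pval_consistency(pval_exposure, beta_exposure, se_exposure, "exposure")
  .check_pval_consistency(pval_outcome, beta_outcome, se_outcome, "outcome")

  x <- data.frame(
    snp = snp,
    effect_allele = if (is.null(effect_allele)) NA_character_ else as.character(effect_allele),
    other_allele = if (is.null(other_allele)) NA_character_ else as.character(other_allele),
    beta_exposure = as.numeric(beta_exposure),
    se_exposure = as.numeric(se_exposure),
    beta_outcome = as.numeric(beta_outcome),
    se_outcome = as.numeric(se_outcome),
    eaf = if (is.null(eaf)) NA_real_ else as.numeric(eaf),
    stringsAsFactors = FALSE
  )
  rownames(x) <- NULL
  class(x) <- c("mr_summary_data", "data.frame")
  attr(x, "K") <- K
  x
}

.check_pval_consistency <- function(p, beta, se, label) {
  if (is.null(p)) return(invisible(NULL))
  ok <- !is.na(p)
  if (!any(ok)) return(invisible(NULL))
  expected <- 2 * stats::pnorm(-abs(beta[ok] / se[ok]))
  rel <- abs(p[ok] - expected) / pmax(expected, .Machine$double.eps)
  if (any(rel > 0.10))
    warning(sum(rel > 0.10), " ", label,
            " p-value(s) disagree with beta/se under a two-sided normal test",
            " by more than 10% relative", call. = FALSE)
  invisible(NULL)
}

#' @export
print.mr_summary_data <- function(x, ...) {
  cat("Summarized Mendelian randomization data:",
      attr(x, "K"), "variant(s)\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Number of variants in a summarized-data object
#' @param x an `mr_summary_data` object.
#' @return integer count of variants.
#' @export
n_variants <- function(x) {
  stopifnot(inherits(x, "mr_summary_data"))
  as.integer(attr(x, "K"))
}

# ---- allele harmonization --------------------------------------------------

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(a1, a2) {
  !is.na(a1) & !is.na(a2) & a1 %in% names(.complement) &
    unname(.complement[a1]) == a2
}

#' Harmonize the outcome association onto the exposure effect allele
#'
#' Aligns which allele the outcome association coefficient refers to so
#' that both sources report effects per copy of the same (exposure)
#' effect allele. If the outcome file reports the effect for the other
#' allele, the coefficient sign is flipped (and the allele frequency
#' replaced by its complement). Palindromic variants (A/T or C/G
#' pairs), whose strand cannot be resolved without allele-frequency
#' evidence, and variants with irreconcilable alleles are flagged for
#' exclusion rather than silently retained.
#'
#' @param exposure,outcome single-variant association records: lists or
#'   one-row data frames with elements `snp` (or `variant_id`),
#'   `effect_allele`, `other_allele`, `beta`, `se` and optionally `eaf`.
#' @return The harmonized outcome record (same shape as `outcome`) with
#'   an added element `action`, one of `"keep"`, `"flip"`, `"exclude"`.
#' @details Harmonization is an involution on the flip case: applying
#'   the swap twice restores the original record. When both records
#'   carry an `eaf`, palindromic variants with clearly matching minor
#'   alleles (both frequencies on the same side of 0.5, away from 0.5
#'   by more than 0.08) are kept; ambiguous ones are excluded.
#' @export
harmonize_alleles <- function(exposure, outcome) {
  ex <- as.list(exposure); ou <- as.list(outcome)
  id_ex <- ex$snp %||% ex$variant_id
  id_ou <- ou$snp %||% ou$variant_id
  if (!identical(as.character(id_ex), as.character(id_ou)))
    stop("harmonize_alleles() requires records for the same variant")

  ea_x <- toupper(as.character(ex$effect_allele))
  oa_x <- toupper(as.character(ex$other_allele %||% NA_character_))
  ea_y <- toupper(as.character(ou$effect_allele))
  oa_y <- toupper(as.character(ou$other_allele %||% NA_character_))

  out <- ou
  pal <- .is_palindromic(ea_x, oa_x)
  if (isTRUE(pal)) {
    fx <- ex$eaf %||% NA_real_; fy <- ou$eaf %||% NA_real_
    resolvable <- !is.na(fx) && !is.na(fy) &&
      abs(fx - 0.5) > 0.08 && abs(fy - 0.5) > 0.08
    if (!resolvable) {
      out$action <- "exclude"
      return(out)
    }
    # frequencies identify the shared allele: same side of 0.5 => aligned
    if ((fx - 0.5) * (fy - 0.5) > 0) {
      out$action <- "keep"
    } else {
      out$beta <- -ou$beta
      out$effect_allele <- oa_y
      out$other_allele <- ea_y
      if (!is.null(out$eaf) && !is.na(out$eaf)) out$eaf <- 1 - out$eaf
      out$action <- "flip"
    }
    return(out)
  }

  if (identical(ea_x, ea_y) && (is.na(oa_x) || is.na(oa_y) || identical(oa_x, oa_y))) {
    out$action <- "keep"
  } else if (identical(ea_x, oa_y) && (is.na(oa_x) || identical(oa_x, ea_y))) {
    out$beta <- -ou$beta
    out$effect_allele <- oa_y
    out$other_allele <- ea_y
    if (!is.null(out$eaf) && !is.na(out$eaf)) out$eaf <- 1 - out$eaf
    out$action <- "flip"
  } else {
    out$action <- "exclude"
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- file I/O --------------------------------------------------------------

.default_columns <- c(snp = "snp", effect_allele = "effect_allele",
                      other_allele = "other_allele", beta = "beta",
                      se = "se", eaf = "eaf", pval = "pval")

.read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.resolve_columns <- function(df, column_map, path, need_alleles = TRUE) {
  map <- .default_columns
  if (length(column_map)) map[names(column_map)] <- unlist(column_map)
  required <- c("snp", "beta", "se", if (need_alleles) "effect_allele")
  for (r in required) {
    if (!map[[r]] %in% names(df))
      stop("required column '", map[[r]], "' (", r, ") not found in ", path)
  }
  get <- function(role) if (map[[role]] %in% names(df)) df[[map[[role]]]] else NULL
  list(snp = as.character(get("snp")),
       effect_allele = get("effect_allele"),
       other_allele = get("other_allele"),
       beta = as.numeric(get("beta")),
       se = as.numeric(get("se")),
       eaf = if (is.null(get("eaf"))) NULL else as.numeric(get("eaf")),
       pval = if (is.null(get("pval"))) NULL else as.numeric(get("pval")))
}

#' Read and harmonize two summary-statistics files
#'
#' Loads per-variant association tables for the exposure and the
#' outcome (tab- or comma-delimited, auto-detected from the header
#' line), restricts to the variants present in both, harmonizes the
#' outcome effect alleles onto the exposure's (see
#' [harmonize_alleles()]), and returns an [mr_summary_data] object in
#' exposure-file order. Counts of dropped and sign-flipped variants are
#' reported via `message()`.
#'
#' @param exposure_path,outcome_path paths to delimited text files with
#'   a header line.
#' @param column_map named list/vector mapping roles
#'   (`snp`, `effect_allele`, `other_allele`, `beta`, `se`, `eaf`,
#'   `pval`) to the column names actually used in the files. Roles not
#'   remapped keep the defaults equal to the role names.
#' @param keep_palindromic keep palindromic variants that lack
#'   allele-frequency evidence instead of excluding them (default
#'   `FALSE`; strand ambiguity can silently corrupt the sign of the
#'   outcome association).
#' @return An [mr_summary_data] object. Variant order is defined by the
#'   exposure file; all downstream matrices must use that order.
#' @export
read_mr_summary <- function(exposure_path, outcome_path, column_map = list(),
                            keep_palindromic = FALSE) {
  ex <- .resolve_columns(.read_delim_auto(exposure_path), column_map, exposure_path)
  ou <- .resolve_columns(.read_delim_auto(outcome_path), column_map, outcome_path)

  common <- ex$snp[ex$snp %in% ou$snp]
  if (length(common) == 0L)
    stop("no overlapping variants between '", exposure_path, "' and '",
         outcome_path, "'")
  n_drop_overlap <- (length(ex$snp) - length(common)) +
    (length(ou$snp) - length(common))

  idx_e <- match(common, ex$snp)
  idx_o <- match(common, ou$snp)

  keep <- logical(length(common))
  flip <- logical(length(common))
  beta_y <- se_y <- numeric(length(common))
  for (i in seq_along(common)) {
    rec_e <- list(snp = common[i],
                  effect_allele = ex$effect_allele[idx_e[i]],
                  other_allele = ex$other_allele[idx_e[i]],
                  beta = ex$beta[idx_e[i]], se = ex$se[idx_e[i]],
                  eaf = ex$eaf[idx_e[i]])
    rec_o <- list(snp = common[i],
                  effect_allele = ou$effect_allele[idx_o[i]],
                  other_allele = ou$other_allele[idx_o[i]],
                  beta = ou$beta[idx_o[i]], se = ou$se[idx_o[i]],
                  eaf = ou$eaf[idx_o[i]])
    h <- harmonize_alleles(rec_e, rec_o)
    if (h$action == "exclude" && keep_palindromic &&
        isTRUE(.is_palindromic(toupper(as.character(rec_e$effect_allele)),
                               toupper(as.character(rec_e$other_allele))))) {
      h$action <- "keep"   # user accepts strand risk
      h$beta <- rec_o$beta
    }
    keep[i] <- h$action != "exclude"
    flip[i] <- h$action == "flip"
    beta_y[i] <- h$beta
    se_y[i] <- rec_o$se
  }
  if (!any(keep))
    stop("all overlapping variants were excluded during allele harmonization")
  message(sum(!keep), " variant(s) excluded by harmonization, ",
          sum(flip), " flipped, ", n_drop_overlap,
          " non-overlapping record(s) dropped")

  mr_summary_data(
    snp = common[keep],
    beta_exposure = ex$beta[idx_e][keep],
    se_exposure = ex$se[idx_e][keep],
    beta_outcome = beta_y[keep],
    se_outcome = se_y[keep],
    effect_allele = ex$effect_allele[idx_e][keep],
    other_allele = if (is.null(ex$other_allele)) NULL else ex$other_allele[idx_e][keep],
    eaf = if (is.null(ex$eaf)) NULL else ex$eaf[idx_e][keep]
  )
}

#' Write a summarized-data object to a pair of delimited files
#'
#' Writes exposure and outcome association tables in the same dialect
#' [read_mr_summary()] reads, with enough digits that reloading
#' reproduces every numeric field exactly.
#'
#' @param x an [mr_summary_data] object.
#' @param exposure_path,outcome_path output file paths (TSV).
#' @return Invisibly, `x`.
#' @export
write_mr_summary <- function(x, exposure_path, outcome_path) {
  stopifnot(inherits(x, "mr_summary_data"))
  fmt <- function(v) sprintf("%.17g", v)
  ea <- ifelse(is.na(x$effect_allele), "A", x$effect_allele)
  oa <- ifelse(is.na(x$other_allele), "G", x$other_allele)
  eafs <- if (all(is.na(x$eaf))) NULL else fmt(x$eaf)
  base <- function(beta, se) {
    d <- data.frame(snp = x$snp, effect_allele = ea, other_allele = oa,
                    beta = fmt(beta), se = fmt(se),
                    stringsAsFactors = FALSE)
    if (!is.null(eafs)) d$eaf <- eafs
    d
  }
  utils::write.table(base(x$beta_exposure, x$se_exposure), exposure_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(base(x$beta_outcome, x$se_outcome), outcome_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

# ---- LD correlation matrix -------------------------------------------------

#' Validate (and optionally regularize) a variant correlation matrix
#'
#' Checks that a matrix of pairwise variant correlations
#' \eqn{\rho_{ij}} is usable as the LD input to the correlated-variant
#' likelihood: symmetric (small asymmetries below 1e-6 are averaged
#' away), unit diagonal, entries in [-1, 1], and positive
#' semi-definite (smallest eigenvalue >= -1e-8). A condition number
#' above 1e8 triggers a warning suggesting variant pruning or ridge
#' regularization \eqn{\rho \to (1-\lambda)\rho + \lambda I}.
#'
#' @param rho square numeric matrix of correlations, with variant IDs
#'   as dimnames when available.
#' @param variant_ids optional character vector of IDs to attach as
#'   dimnames (overrides existing ones).
#' @param ridge ridge weight \eqn{\lambda} in [0, 1) applied as
#'   \eqn{(1-\lambda)\rho + \lambda I}; default 0 (off).
#' @return A matrix of class `mr_ld_matrix`.
#' @export
mr_ld_matrix <- function(rho, variant_ids = NULL, ridge = 0) {
  rho <- as.matrix(rho)
  if (nrow(rho) != ncol(rho)) stop("correlation matrix must be square")
  asym <- max(abs(rho - t(rho)))
  if (asym >= 1e-6)
    stop("correlation matrix is asymmetric (max |rho - t(rho)| = ",
         format(asym), ")")
  rho <- (rho + t(rho)) / 2
  if (max(abs(diag(rho) - 1)) > 1e-8)
    stop("correlation matrix must have unit diagonal")
  if (any(rho < -1 - 1e-12 | rho > 1 + 1e-12))
    stop("correlation entries must lie in [-1, 1]")
  if (ridge < 0 || ridge >= 1) stop("'ridge' must lie in [0, 1)")
  if (ridge > 0) {
    rho <- (1 - ridge) * rho + ridge * diag(nrow(rho))
  }
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("correlation matrix is not positive semi-definite ",
         "(smallest eigenvalue ", format(min(ev)),
         "); prune correlated variants or use 'ridge'")
  if (min(ev) > 0 && max(ev) / min(ev) > 1e8)
    warning("correlation matrix is near-singular (condition number ",
            format(max(ev) / min(ev), digits = 3),
            "); consider pruning variants or ridge regularization",
            call. = FALSE)
  if (!is.null(variant_ids)) dimnames(rho) <- list(variant_ids, variant_ids)
  class(rho) <- c("mr_ld_matrix", "matrix", "array")
  rho
}

#' Read a labelled LD correlation matrix and align it to a variant order
#'
#' Reads a square tab- or comma-delimited matrix whose row and column
#' labels are variant IDs, reorders rows and columns to `variant_order`
#' (the exposure-file order of the analysis), and validates it with
#' [mr_ld_matrix()].
#'
#' @param path path to the delimited matrix file; first column holds
#'   row labels.
#' @param variant_order character vector of variant IDs defining the
#'   required order; every ID must be present in the file.
#' @param ridge passed to [mr_ld_matrix()].
#' @return A matrix of class `mr_ld_matrix` in `variant_order`.
#' @export
read_ld_matrix <- function(path, variant_order, ridge = 0) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  m <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                         check.names = FALSE)
  m <- as.matrix(m)
  missing <- setdiff(variant_order, rownames(m))
  if (length(missing))
    stop("LD matrix is missing variant(s): ", paste(missing, collapse = ", "))
  missing_c <- setdiff(variant_order, colnames(m))
  if (length(missing_c))
    stop("LD matrix is missing column(s): ", paste(missing_c, collapse = ", "))
  m <- m[variant_order, variant_order, drop = FALSE]
  mr_ld_matrix(m, variant_ids = variant_order, ridge = ridge)
}
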