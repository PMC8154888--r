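#' Specify an animal model
#'
#' Describes one trait's linear mixed animal model: the response, fixed
#' class effects (e.g. test day, sex), continuous covariates (e.g. body
#' weight at testing), and which random terms to fit. The additive genetic
#' effect has covariance proportional to the pedigree relationship matrix;
#' the common-environment ("hapa") effect is shared by full sibs reared in
#' the same net enclosure and is confounded with family in this design.
#'
#' @param response trait column name.
#' @param fixed character vector of class-variable column names.
#' @param covariates character vector of continuous covariate columns.
#' @param random subset of \code{c("additive", "common_env")}.
#' @return An object of class \code{model_spec}.
#' @export
model_spec <- function(response, fixed = "test_day", covariates = character(),
                       random = c("additive", "common_env")) {
  stopifnot(is.character(response), length(response) == 1L)
  random <- match.arg(random, c("additive", "common_env"),
                      several.ok = TRUE)
  if (response %in% covariates)
    stop("response cannot also be a covariate", call. = FALSE)
  structure(list(response = response, fixed = as.character(fixed),
                 covariates = as.character(covariates),
                 random = unique(random)),
            class = "model_spec")
}

# full-sib family label per pedigree animal; animals without both parents
# known get a singleton family of their own
family_labels <- function(ped) {
  ifelse(!is.na(ped$sire) & !is.na(ped$dam),
         paste(ped$sire, ped$dam, sep = ":"),
         paste0("singleton:", ped$animal))
}

#' Build design matrices for an animal model
#'
#' Assembles the response vector, fixed-effect matrix X (treatment coding,
#' intercept included), the animal incidence matrix Z1 (columns = all
#' pedigree animals) and the full-sib family incidence matrix Z2 (hapa
#' effect) from a phenotype table. Rows with a missing response, covariate
#' or fixed-effect level are dropped; \code{n_used} records what remains.
#' The pedigree's sparse A-inverse is computed once and carried along for
#' the REML fit.
#'
#' @param table phenotype data.frame with a \code{fish_id} column.
#' @param spec a \code{\link{model_spec}}.
#' @param ped a \code{\link{pedigree}} covering every phenotyped fish.
#' @param ainv optionally, a precomputed \code{\link{a_inverse}(ped)} to
#'   share across bundles built from the same pedigree.
#' @return An object of class \code{design_bundle}.
#' @export
build_design <- function(table, spec, ped, ainv = NULL) {
  stopifnot(is.data.frame(table), inherits(spec, "model_spec"),
            inherits(ped, "pedigree"))
  if (!"fish_id" %in% names(table))
    stop("phenotype table needs a 'fish_id' column", call. = FALSE)
  used <- c(spec$response, spec$fixed, spec$covariates)
  missing_cols <- setdiff(used, names(table))
  if (length(missing_cols))
    stop("column(s) absent from phenotype table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  keep <- rep(TRUE, nrow(table))
  for (cl in used) keep <- keep & !is.na(table[[cl]])
  dat <- table[keep, , drop = FALSE]
  if (nrow(dat) == 0L)
    stop("no usable records after missing-data exclusion", call. = FALSE)
  aidx <- match(as.character(dat$fish_id), ped$animal)
  if (anyNA(aidx))
    stop("phenotyped animal(s) absent from pedigree: ",
         paste(utils::head(dat$fish_id[is.na(aidx)], 5L), collapse = ", "),
         call. = FALSE)
  # fixed-effect matrix, treatment coding with intercept
  for (f in spec$fixed) dat[[f]] <- factor(dat[[f]])
  rhs <- if (length(c(spec$fixed, spec$covariates)))
    paste(c(spec$fixed, spec$covariates), collapse = " + ") else "1"
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("fixed-effect matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  n <- nrow(dat)
  Z1 <- Matrix::sparseMatrix(i = seq_len(n), j = aidx, x = 1,
                             dims = c(n, nrow(ped)),
                             dimnames = list(NULL, ped$animal))
  fam_all <- family_labels(ped)
  fam <- fam_all[aidx]
  fam_levels <- unique(fam_all)
  Z2 <- Matrix::sparseMatrix(i = seq_len(n), j = match(fam, fam_levels),
                             x = 1, dims = c(n, length(fam_levels)),
                             dimnames = list(NULL, fam_levels))
  keep_fam <- Matrix::colSums(Z2) > 0
  Z2 <- Z2[, keep_fam, drop = FALSE]
  if (is.null(ainv)) ainv <- a_inverse(ped)
  structure(list(y = as.numeric(dat[[spec$response]]), X = X, Z1 = Z1,
                 Z2 = Z2, animal_idx = aidx,
                 animal = ped$animal[aidx], family = fam,
                 spec = spec, ped = ped, ainv = ainv,
                 n_used = n, n_dropped = sum(!keep)),
            class = "design_bundle")
}

#' @method print design_bundle
#' @export
print.design_bundle <- function(x, ...) {
  cat("Animal-model design:", x$spec$response, "~",
      paste(c(x$spec$fixed, x$spec$covariates), collapse = " + "), "\n")
  cat("  records:", x$n_used, "(", x$n_dropped, "dropped )",
      " fixed columns:", ncol(x$X),
      " animals:", ncol(x$Z1), " families:", ncol(x$Z2), "\n")
  cat("  random:", paste(x$spec$random, collapse = " + "), "\n")
  invisible(x)
}
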