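#' Construct a validated pedigree
#'
#' Builds a topologically sorted pedigree (parents before offspring) from
#' animal/sire/dam triples. Unknown parents may be coded \code{0}, the empty
#' string, \code{"NA"} or \code{NA}. Parents that never appear as animals
#' are added as founder records with a warning. Duplicated animal ids and
#' ancestry cycles (including self-parenting) are errors.
#'
#' @param animal,sire,dam vectors of ids (coerced to character).
#' @return An object of class \code{pedigree}: a data.frame with columns
#'   \code{animal}, \code{sire}, \code{dam} (character, \code{NA} for
#'   unknown) in topological order, plus integer attribute columns
#'   \code{sire_idx}/\code{dam_idx} giving row positions of the parents.
#' @export
pedigree <- function(animal, sire, dam) {
  norm <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x %in% c("0", "", "NA")] <- NA_character_
    x
  }
  animal <- as.character(animal)
  sire <- norm(rep_len(as.character(sire), length(animal)))
  dam <- norm(rep_len(as.character(dam), length(animal)))
  if (anyNA(animal) || any(animal %in% c("0", "")))
    stop("animal ids must be non-missing", call. = FALSE)
  if (anyDuplicated(animal))
    stop("duplicate animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "),
         call. = FALSE)
  parents <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(parents)) {
    warning(length(parents),
            " parent id(s) had no own record; added as founders",
            call. = FALSE)
    animal <- c(parents, animal)
    sire <- c(rep(NA_character_, length(parents)), sire)
    dam <- c(rep(NA_character_, length(parents)), dam)
  }
  n <- length(animal)
  si <- match(sire, animal)
  di <- match(dam, animal)
  # Kahn topological sort on the parent -> offspring DAG
  indeg <- (!is.na(si)) + (!is.na(di))
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        if (p == i) stop("animal '", animal[i], "' is its own parent",
                         call. = FALSE)
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  order_out <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order_out <- c(order_out, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order_out) < n)
    stop("pedigree contains an ancestry cycle involving: ",
         paste(animal[setdiff(seq_len(n), order_out)], collapse = ", "),
         call. = FALSE)
  animal <- animal[order_out]; sire <- sire[order_out]; dam <- dam[order_out]
  out <- data.frame(animal = animal, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)
  out$sire_idx <- match(sire, animal)
  out$dam_idx <- match(dam, animal)
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Read a pedigree file
#'
#' Three-column CSV/TSV (animal, sire, dam); a header line is detected and
#' used if its first field is non-numeric and named like "animal"/"id".
#' Unknown parents coded as 0, empty or NA.
#'
#' @param path file path.
#' @return A \code{\link{pedigree}}.
#' @export
read_pedigree <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  header <- any(grepl("^(animal|id|sire|dam)$", tolower(trimws(first))))
  tab <- utils::read.table(path, header = header, sep = sep,
                           na.strings = c("", "NA"), colClasses = "character")
  if (ncol(tab) < 3L)
    stop("pedigree file needs three columns: animal, sire, dam",
         call. = FALSE)
  pedigree(tab[[1L]], tab[[2L]], tab[[3L]])
}

#' @method print pedigree
#' @export
print.pedigree <- function(x, ...) {
  founders <- sum(is.na(x$sire_idx) & is.na(x$dam_idx))
  cat("Pedigree:", nrow(x), "animals (", founders, "founders )\n")
  print(utils::head(as.data.frame(x)[, 1:3]), row.names = FALSE)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Numerator relationship matrix by the tabular method
#'
#' Builds the additive (numerator) relationship matrix A over all animals in
#' the pedigree: founders have diagonal 1, an animal's relationship with any
#' older animal is the mean of its parents' relationships with that animal,
#' and its diagonal is \eqn{1 + F} with inbreeding \eqn{F} equal to half the
#' parents' relationship. Founders are taken as unrelated and non-inbred.
#'
#' @param ped a \code{\link{pedigree}}.
#' @return Symmetric dense matrix with dimnames = animal ids.
#' @export
relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  si <- ped$sire_idx; di <- ped$dam_idx
  for (i in seq_len(n)) {
    if (i > 1L) {
      j <- seq_len(i - 1L)
      rel <- numeric(i - 1L)
      if (!is.na(si[i])) rel <- rel + 0.5 * A[j, si[i]]
      if (!is.na(di[i])) rel <- rel + 0.5 * A[j, di[i]]
      A[j, i] <- rel
      A[i, j] <- rel
    }
    A[i, i] <- 1 + if (!is.na(si[i]) && !is.na(di[i]))
      0.5 * A[si[i], di[i]] else 0
  }
  A
}

#' Inbreeding coefficients
#'
#' \eqn{F_i} is half the additive relationship between the parents of
#' \eqn{i}; founders and animals with an unknown parent have \eqn{F = 0}
#' under the unrelated-founder assumption.
#'
#' @param ped a \code{\link{pedigree}}.
#' @return Named numeric vector of F, in pedigree order.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  A <- relationship_matrix(ped)
  stats::setNames(diag(A) - 1, ped$animal)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Direct construction of \eqn{A^{-1}} by Henderson's rules with inbreeding
#' accounted for: each animal contributes \eqn{1/d_i} to the equations,
#' where \eqn{d_i = 1 - 0.25(1+F_s) - 0.25(1+F_d)} (terms only for known
#' parents) is its Mendelian-sampling variance. The log-determinant of A,
#' \eqn{\sum_i \log d_i}, is attached as attribute \code{"logdet"}; it is
#' needed by the REML likelihood.
#'
#' @param ped a \code{\link{pedigree}}.
#' @param f optional precomputed inbreeding coefficients (pedigree order).
#' @return A sparse symmetric \code{Matrix} with attribute \code{logdet}.
#' @export
a_inverse <- function(ped, f = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  si <- ped$sire_idx; di <- ped$dam_idx
  if (is.null(f)) f <- pedigree_inbreeding_fast(ped)
  d <- 1 - ifelse(is.na(si), 0, 0.25 * (1 + f[ifelse(is.na(si), 1L, si)])) -
    ifelse(is.na(di), 0, 0.25 * (1 + f[ifelse(is.na(di), 1L, di)]))
  alpha <- 1 / d
  # accumulate triplets, vectorised over animals
  ii <- seq_len(n); jj <- seq_len(n); xx <- alpha
  ks <- which(!is.na(si)); kd <- which(!is.na(di))
  kb <- which(!is.na(si) & !is.na(di))
  ii <- c(ii, ks, si[ks], si[ks])
  jj <- c(jj, si[ks], ks, si[ks])
  xx <- c(xx, -alpha[ks] / 2, -alpha[ks] / 2, alpha[ks] / 4)
  ii <- c(ii, kd, di[kd], di[kd])
  jj <- c(jj, di[kd], kd, di[kd])
  xx <- c(xx, -alpha[kd] / 2, -alpha[kd] / 2, alpha[kd] / 4)
  ii <- c(ii, si[kb], di[kb])
  jj <- c(jj, di[kb], si[kb])
  xx <- c(xx, alpha[kb] / 4, alpha[kb] / 4)
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Ainv <- methods::as(Matrix::forceSymmetric(Ainv), "CsparseMatrix")
  attr(Ainv, "logdet") <- sum(log(d))
  Ainv
}
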