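#' Build a validated, topologically sorted pedigree
#'
#' Takes a data frame of animal/sire/dam records and returns a `pedigree`
#' tibble sorted so that every parent precedes its offspring, with dense
#' internal integer codes used by the matrix machinery.  Original
#' identifiers are preserved and used in all outputs.
#'
#' @param x A data frame with columns `animal`, `sire`, `dam` and optionally
#'   `sex` (`"F"`/`"M"`) and `sr` (selection round, non-negative integer).
#'   Unknown parents are coded `NA`, `""` or `"0"`.
#' @param missing_parent What to do when a parent identifier never appears as
#'   an animal: `"error"` (default) or `"founder"` to auto-insert it as a
#'   founder record.
#' @return A tibble of class `pedigree` in topological order with columns
#'   `animal`, `sire`, `dam`, `sex`, `sr` plus internal index columns
#'   `.sire`, `.dam` (0 = unknown).
#' @examples
#' ped <- as_pedigree(data.frame(
#'   animal = c("calf", "bull", "cow"),
#'   sire   = c("bull", NA, NA),
#'   dam    = c("cow", NA, NA)
#' ))
#' ped$animal # parents first
#' @export
as_pedigree <- function(x, missing_parent = c("error", "founder")) {
  missing_parent <- match.arg(missing_parent)
  x <- as.data.frame(x)
  names(x) <- tolower(names(x))
  req <- c("animal", "sire", "dam")
  if (!all(req %in% names(x))) {
    stop("pedigree needs columns 'animal', 'sire', 'dam'", call. = FALSE)
  }
  clean_id <- function(v) {
    v <- as.character(v)
    v[!is.na(v) & (v == "" | v == "0")] <- NA_character_
    v
  }
  animal <- clean_id(x$animal)
  sire <- clean_id(x$sire)
  dam <- clean_id(x$dam)
  if (anyNA(animal)) stop("missing animal identifier", call. = FALSE)
  if (anyDuplicated(animal)) {
    stop("duplicated animal identifier: ", animal[duplicated(animal)][1],
      call. = FALSE
    )
  }
  sex <- if ("sex" %in% names(x)) toupper(as.character(x$sex)) else rep(NA_character_, length(animal))
  sr <- if ("sr" %in% names(x)) as.integer(x$sr) else rep(NA_integer_, length(animal))

  undefined <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(undefined)) {
    if (missing_parent == "error") {
      stop(
        "parent never defined as an animal: ", undefined[1],
        " (use missing_parent = \"founder\" to auto-insert)",
        call. = FALSE
      )
    }
    f_sex <- ifelse(undefined %in% sire, "M", "F")
    animal <- c(animal, undefined)
    sire <- c(sire, rep(NA_character_, length(undefined)))
    dam <- c(dam, rep(NA_character_, length(undefined)))
    sex <- c(sex, f_sex)
    sr <- c(sr, rep(NA_integer_, length(undefined)))
  }

  self <- which(animal == sire | animal == dam)
  if (length(self)) {
    stop("pedigree cycle detected involving animal ", animal[self[1]], call. = FALSE)
  }
  sex_by_id <- stats::setNames(sex, animal)
  bad_dam <- stats::na.omit(dam)[!is.na(sex_by_id[stats::na.omit(dam)]) &
    sex_by_id[stats::na.omit(dam)] == "M"]
  if (length(bad_dam)) {
    stop("animal ", bad_dam[1], " is used as a dam but has sex M", call. = FALSE)
  }
  bad_sire <- stats::na.omit(sire)[!is.na(sex_by_id[stats::na.omit(sire)]) &
    sex_by_id[stats::na.omit(sire)] == "F"]
  if (length(bad_sire)) {
    stop("animal ", bad_sire[1], " is used as a sire but has sex F", call. = FALSE)
  }

  ## Kahn topological sort, stable in input order
  n <- length(animal)
  ix <- stats::setNames(seq_len(n), animal)
  ps <- ifelse(is.na(sire), 0L, ix[sire])
  pd <- ifelse(is.na(dam), 0L, ix[dam])
  indeg <- (ps > 0L) + (pd > 0L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (ps[i] > 0L) children[[ps[i]]] <- c(children[[ps[i]]], i)
    if (pd[i] > 0L) children[[pd[i]]] <- c(children[[pd[i]]], i)
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    i <- queue[1]
    queue <- queue[-1]
    order <- c(order, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    cyc <- setdiff(seq_len(n), order)[1]
    stop("pedigree cycle detected involving animal ", animal[cyc], call. = FALSE)
  }

  animal <- animal[order]
  sire <- sire[order]
  dam <- dam[order]
  sex <- sex[order]
  sr <- sr[order]
  ix <- stats::setNames(seq_along(animal), animal)
  out <- tibble::tibble(
    animal = animal, sire = sire, dam = dam, sex = sex, sr = sr,
    .sire = ifelse(is.na(sire), 0L, unname(ix[sire])),
    .dam = ifelse(is.na(dam), 0L, unname(ix[dam]))
  )
  class(out) <- c("pedigree", class(out))
  out
}

#' @export
print.pedigree <- function(x, ...) {
  cat(
    "<pedigree> ", nrow(x), " animals (",
    sum(x$.sire == 0L & x$.dam == 0L), " founders)\n",
    sep = ""
  )
  NextMethod()
}

is_pedigree <- function(x) inherits(x, "pedigree")

check_pedigree <- function(pedigree) {
  if (!is_pedigree(pedigree)) {
    pedigree <- as_pedigree(pedigree)
  }
  pedigree
}

#' Inbreeding coefficients
#'
#' Computes the per-animal inbreeding coefficient F by the Meuwissen-Luo
#' recursion on the sorted pedigree.  Founders (and any animal with an
#' unknown parent) have F = 0.
#'
#' @param pedigree A [as_pedigree()] object (or a coercible data frame).
#' @return A tibble with columns `animal` and `f`.
#' @export
inbreeding <- function(pedigree) {
  pedigree <- check_pedigree(pedigree)
  f <- ml_inbreeding_cpp(pedigree$.sire, pedigree$.dam)
  tibble::tibble(animal = pedigree$animal, f = as.numeric(f))
}

inbreeding_vec <- function(pedigree, use_inbreeding = TRUE) {
  if (!use_inbreeding) {
    return(numeric(nrow(pedigree)))
  }
  as.numeric(ml_inbreeding_cpp(pedigree$.sire, pedigree$.dam))
}

#' Sparse inverse numerator relationship matrix
#'
#' Builds A-inverse directly by Henderson's rules, with the exact
#' inbreeding adjustment by default (Mendelian sampling variances from the
#' Meuwissen-Luo coefficients).  Each animal contributes at most nine
#' entries, so the result is sparse for any pedigree size.
#'
#' @inheritParams inbreeding
#' @param use_inbreeding If `TRUE` (default) use inbreeding-adjusted
#'   Mendelian sampling variances; `FALSE` gives the textbook rules for a
#'   non-inbred pedigree.
#' @return A symmetric sparse matrix (`Matrix::dsCMatrix`) with animal
#'   identifiers as dimnames.
#' @export
a_inverse <- function(pedigree, use_inbreeding = TRUE) {
  pedigree <- check_pedigree(pedigree)
  n <- nrow(pedigree)
  s <- pedigree$.sire
  d <- pedigree$.dam
  f <- inbreeding_vec(pedigree, use_inbreeding)
  md <- rep(1, n)
  both <- s > 0L & d > 0L
  sonly <- s > 0L & d == 0L
  donly <- d > 0L & s == 0L
  md[both] <- 0.5 - 0.25 * (f[s[both]] + f[d[both]])
  md[sonly] <- 0.75 - 0.25 * f[s[sonly]]
  md[donly] <- 0.75 - 0.25 * f[d[donly]]
  b <- 1 / md
  an <- seq_len(n)
  hs <- s > 0L
  hd <- d > 0L
  ii <- c(an, an[hs], an[hd], s[hs], d[hd], pmax(s, d)[both])
  jj <- c(an, s[hs], d[hd], s[hs], d[hd], pmin(s, d)[both])
  xx <- c(b, -0.5 * b[hs], -0.5 * b[hd], 0.25 * b[hs], 0.25 * b[hd], 0.25 * b[both])
  low <- ii >= jj
  out <- Matrix::sparseMatrix(
    i = ifelse(low, ii, jj), j = ifelse(low, jj, ii), x = xx,
    dims = c(n, n), symmetric = TRUE,
    dimnames = list(pedigree$animal, pedigree$animal)
  )
  out
}

#' Additive relationship submatrix
#'
#' Dense block of the numerator relationship matrix A for a subset of
#' animals, computed by multiplying indicator columns through the
#' pedigree recursion (no full A is ever formed), so it works for large
#' pedigrees.  The diagonal equals 1 + F.
#'
#' @inheritParams inbreeding
#' @param animals Character vector of animal identifiers.
#' @return A dense symmetric matrix with `animals` as dimnames.
#' @export
relationship_submatrix <- function(pedigree, animals) {
  pedigree <- check_pedigree(pedigree)
  ix <- match(animals, pedigree$animal)
  if (anyNA(ix)) {
    stop("unknown animal in subset: ", animals[is.na(ix)][1], call. = FALSE)
  }
  n <- nrow(pedigree)
  E <- matrix(0, n, length(ix))
  E[cbind(ix, seq_along(ix))] <- 1
  f <- inbreeding_vec(pedigree, TRUE)
  AE <- a_mult_cpp(pedigree$.sire, pedigree$.dam, f, E)
  out <- AE[ix, , drop = FALSE]
  out <- (out + t(out)) / 2
  dimnames(out) <- list(animals, animals)
  out
}

## A %*% x for a vector/matrix indexed in pedigree order (internal).
a_times <- function(pedigree, x, f = NULL) {
  if (is.null(f)) f <- inbreeding_vec(pedigree, TRUE)
  x <- as.matrix(x)
  a_mult_cpp(pedigree$.sire, pedigree$.dam, f, x)
}

a_logdet <- function(pedigree, f = NULL) {
  if (is.null(f)) f <- inbreeding_vec(pedigree, TRUE)
  a_logdet_cpp(pedigree$.sire, pedigree$.dam, f)
}

#' Read a pedigree file
#'
#' Delimited text with header `animal,sire,dam,sex,sr`; `0` or empty marks
#' an unknown parent; sex is `F`/`M`.
#'
#' @param path File path.
#' @param sep Field separator, default comma.
#' @inheritParams as_pedigree
#' @return A [as_pedigree()] object.
#' @export
read_pedigree <- function(path, sep = ",", missing_parent = c("error", "founder")) {
  x <- utils::read.table(path,
    header = TRUE, sep = sep, colClasses = "character",
    strip.white = TRUE
  )
  if ("sr" %in% tolower(names(x))) x$sr <- suppressWarnings(as.integer(x$sr))
  as_pedigree(x, missing_parent = match.arg(missing_parent))
}
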