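#' Topological order of a pedigree
#'
#' Orders individuals so that parents precede children; errors on cycles,
#' naming the individuals involved.
#' @param ped pedigree data.frame (individual_id, father_id, mother_id).
#' @return character vector of ids in topological order.
#' @keywords internal
.pedigreeOrder <- function(ped) {
  ids <- ped$individual_id
  father <- ped$father_id
  mother <- ped$mother_id
  # parents outside the pedigree are treated as founders
  father[!father %in% ids] <- NA
  mother[!mother %in% ids] <- NA
  placed <- logical(length(ids))
  names(placed) <- ids
  ord <- character(0)
  repeat {
    ready <- !placed &
      (is.na(father) | placed[match(father, ids)]) &
      (is.na(mother) | placed[match(mother, ids)])
    if (!any(ready)) break
    ord <- c(ord, ids[ready])
    placed[ready] <- TRUE
  }
  if (!all(placed))
    stop("cyclic pedigree involving: ",
         paste(ids[!placed], collapse = ", "))
  ord
}

#' Kinship matrix of a pedigree
#'
#' Computes the kinship coefficient phi (probability of identity by descent
#' at a random autosomal locus) between all pairs in the pedigree by the
#' standard recursion: founders are mutually unrelated with
#' \eqn{\phi(a,a) = 1/2}; for a non-founder a with parents f, m and any b
#' that is not a descendant of a, \eqn{\phi(a,b) =
#' (\phi(f,b) + \phi(m,b))/2} (missing parents contribute 0), and
#' \eqn{\phi(a,a) = (1 + \phi(f,m))/2}.  Processing individuals in
#' topological (parents-first) order makes the recursion well-defined.
#' Parents referenced but absent from the pedigree are treated as unique
#' unrelated founders.
#'
#' @param ped pedigree data.frame with columns \code{individual_id},
#'   \code{father_id}, \code{mother_id} (NA for missing).
#' @return symmetric numeric matrix of phi with individual ids as dimnames.
#' @examples
#' ped <- data.frame(individual_id = c("f", "m", "c"),
#'                   father_id = c(NA, NA, "f"),
#'                   mother_id = c(NA, NA, "m"))
#' kinshipMatrix(ped)["f", "c"]   # 0.25, i.e. relatedness 0.5
#' @export
kinshipMatrix <- function(ped) {
  stopifnot(all(c("individual_id", "father_id", "mother_id") %in% names(ped)))
  if (anyDuplicated(ped$individual_id))
    stop("duplicate individual ids in pedigree")
  ord <- .pedigreeOrder(ped)
  n <- length(ord)
  idx <- setNames(seq_len(n), ord)
  fa <- idx[ped$father_id[match(ord, ped$individual_id)]]
  mo <- idx[ped$mother_id[match(ord, ped$individual_id)]]
  phi <- matrix(0, n, n, dimnames = list(ord, ord))
  for (k in seq_len(n)) {
    f <- fa[k]; m <- mo[k]
    if (k > 1L) {
      prev <- seq_len(k - 1L)
      v <- numeric(k - 1L)
      if (!is.na(f)) v <- v + phi[f, prev]
      if (!is.na(m)) v <- v + phi[m, prev]
      phi[k, prev] <- v / 2
      phi[prev, k] <- v / 2
    }
    phi[k, k] <- 0.5 * (1 + if (!is.na(f) && !is.na(m)) phi[f, m] else 0)
  }
  phi
}

#' Kinship coefficient between two individuals
#'
#' @param ped pedigree data.frame, see \code{\link{kinshipMatrix}}.
#' @param a,b individual ids.
#' @return phi(a, b).  Relatedness for non-inbred pairs is \code{2 * phi}.
#' @export
kinshipCoefficient <- function(ped, a, b) {
  if (!all(c(a, b) %in% ped$individual_id))
    stop("unknown individual: ",
         paste(setdiff(c(a, b), ped$individual_id), collapse = ", "))
  kinshipMatrix(ped)[a, b]
}

#' Mean pairwise relatedness between families
#'
#' For each pair of families i != j, the mean over all cross-family member
#' pairs (a in i, b in j) of the relatedness r(a, b) = 2 phi(a, b).  The
#' diagonal (within-family relatedness) is not defined and is set to NA.
#'
#' @param village a \linkS4class{Village}.
#' @return symmetric matrix with family ids as dimnames, entries in [0, 1]
#'   off the diagonal.
#' @export
familyRelatedness <- function(village) {
  ped <- pedigree(village)
  fids <- familyIds(village)
  phi <- kinshipMatrix(ped)
  fam <- ped$family_id[match(rownames(phi), ped$individual_id)]
  if (any(table(fam) == 0)) stop("empty family")
  # mean over cross pairs of 2*phi: average phi blockwise then double
  grp <- factor(fam, levels = fids)
  blk <- rowsum(t(rowsum(phi, grp, reorder = TRUE)), grp, reorder = TRUE)
  blk <- blk[fids, fids, drop = FALSE]
  cnt <- as.numeric(table(grp)[fids])
  R <- 2 * blk / outer(cnt, cnt)
  dimnames(R) <- list(fids, fids)
  R <- (R + t(R)) / 2
  diag(R) <- NA_real_
  R
}

#' Great-circle distance by the spherical law of cosines
#'
#' \deqn{d = R \arccos(\sin\phi_1 \sin\phi_2 +
#'   \cos\phi_1 \cos\phi_2 \cos(\lambda_2 - \lambda_1))}
#' with \eqn{R = 6371} km (mean Earth radius) and the cosine argument
#' clamped to [-1, 1] against rounding.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @return distance in kilometers.
#' @examples
#' sphericalDistance(0, 0, 0, 1)   # ~111.19 km, one degree at the equator
#' @export
sphericalDistance <- function(lat1, lon1, lat2, lon2) {
  toRad <- pi / 180
  p1 <- lat1 * toRad; p2 <- lat2 * toRad
  dl <- (lon2 - lon1) * toRad
  arg <- sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)
  6371 * acos(pmin(1, pmax(-1, arg)))
}

#' Pairwise household distances of a village
#'
#' @param village a \linkS4class{Village}.
#' @return symmetric matrix of kilometers with zero diagonal.
#' @export
familyDistances <- function(village) {
  fam <- families(village)
  n <- nrow(fam)
  D <- matrix(0, n, n, dimnames = list(fam$family_id, fam$family_id))
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    d <- sphericalDistance(fam$lat[i], fam$lon[i], fam$lat[j], fam$lon[j])
    D[i, j] <- d
    D[j, i] <- d
  }
  D
}

#' Kin class of a dyad
#'
#' Classifies mean relatedness into \code{close_kin} (r >= 0.25, boundary
#' included), \code{distant_kin} (0 < r < 0.25) and \code{non_kin} (r = 0).
#' The dynamical analysis uses the binary split close (r >= threshold) vs
#' not close.
#'
#' @param r numeric vector of mean relatedness values in [0, 1].
#' @param threshold close-kin boundary, default 0.25.
#' @return character vector of class labels.
#' @export
kinClass <- function(r, threshold = 0.25) {
  stopifnot(all(r >= 0 & r <= 1, na.rm = TRUE))
  ifelse(is.na(r), NA_character_,
         ifelse(r >= threshold, "close_kin",
                ifelse(r > 0, "distant_kin", "non_kin")))
}

#' Write a square family matrix as CSV
#' @param m matrix with family-id dimnames.
#' @param path output file.
#' @export
writeFamilyMatrix <- function(m, path) {
  write.csv(as.data.frame(m), path, row.names = TRUE)
}

#' Read a square family matrix written by \code{writeFamilyMatrix}
#' @param path CSV file.
#' @return numeric matrix.
#' @export
readFamilyMatrix <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
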