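#' Validate and topologically order a pedigree table
#'
#' Checks a pedigree data frame (columns \code{id}, \code{dam}, \code{sire},
#' and optionally \code{sex}, \code{generation}) and returns it reordered so
#' that every parent row precedes all of its offspring rows. Unknown parents
#' (\code{NA} or the string \code{"NA"} or \code{""}) are normalized to
#' \code{NA}. Founders are rows with both parents unknown.
#'
#' @param ped data frame with at least columns \code{id}, \code{dam},
#'   \code{sire}; optional \code{sex} (\code{"female"}, \code{"male"} or
#'   \code{"unknown"}) and \code{generation}.
#' @return The validated pedigree, rows ordered parents-before-offspring,
#'   with class \code{c("pedigree_table", "data.frame")}.
#' @details Errors on duplicated ids, parents that do not appear as rows,
#'   ancestry cycles, individuals listed as their own parent, dams of known
#'   male sex, and sires of known female sex.
#' @examples
#' ped <- data.frame(id = c("o1", "d1", "s1"),
#'                   dam = c("d1", NA, NA), sire = c("s1", NA, NA))
#' validate_pedigree(ped)
#' @export
validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped))
  need <- c("id", "dam", "sire")
  miss <- setdiff(need, names(ped))
  if (length(miss) > 0L)
    stop("pedigree is missing column(s): ", paste(miss, collapse = ", "))

  norm <- function(x) {
    x <- as.character(x)
    x[x %in% c("NA", "", "0")] <- NA_character_
    x
  }
  ped$id <- as.character(ped$id)
  ped$dam <- norm(ped$dam)
  ped$sire <- norm(ped$sire)
  if (!("sex" %in% names(ped))) ped$sex <- "unknown"
  ped$sex <- as.character(ped$sex)
  ped$sex[is.na(ped$sex)] <- "unknown"
  bad_sex <- setdiff(unique(ped$sex), c("female", "male", "unknown"))
  if (length(bad_sex) > 0L)
    stop("unrecognized sex label(s): ", paste(bad_sex, collapse = ", "))

  if (anyDuplicated(ped$id))
    stop("duplicate id(s) in pedigree: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  if (any(ped$dam == ped$id, na.rm = TRUE) ||
      any(ped$sire == ped$id, na.rm = TRUE))
    stop("individual listed as its own parent")

  parents <- setdiff(stats::na.omit(c(ped$dam, ped$sire)), ped$id)
  if (length(parents) > 0L)
    stop("parent(s) not present as pedigree rows: ",
         paste(parents, collapse = ", "))

  # sex consistency of parental roles
  sex_of <- stats::setNames(ped$sex, ped$id)
  dams <- unique(stats::na.omit(ped$dam))
  sires <- unique(stats::na.omit(ped$sire))
  if (any(sex_of[dams] == "male"))
    stop("dam(s) recorded as male: ",
         paste(dams[sex_of[dams] == "male"], collapse = ", "))
  if (any(sex_of[sires] == "female"))
    stop("sire(s) recorded as female: ",
         paste(sires[sex_of[sires] == "female"], collapse = ", "))
  both <- intersect(dams, sires)
  if (length(both) > 0L)
    stop("individual(s) appear both as dam and as sire: ",
         paste(both, collapse = ", "))

  # Kahn topological sort; a leftover means an ancestry cycle.
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  dam_i <- unname(idx[ped$dam])
  sire_i <- unname(idx[ped$sire])
  # number of unplaced parents per row
  indeg <- as.integer(!is.na(dam_i)) + as.integer(!is.na(sire_i))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(dam_i[i], sire_i[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  order_out <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue) > 0L) {
    # keep input order among ties for reproducibility
    queue <- sort(queue)
    i <- queue[1L]
    queue <- queue[-1L]
    order_out <- c(order_out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order_out) < n)
    stop("pedigree contains an ancestry cycle involving: ",
         paste(ped$id[setdiff(seq_len(n), order_out)], collapse = ", "))

  out <- ped[order_out, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree_table", "data.frame")
  out
}

#' Additive (numerator) relationship matrix from a pedigree
#'
#' Builds the additive relationship matrix A by the standard tabular method,
#' processing individuals parents-first: the diagonal is
#' \eqn{A_{ii} = 1 + \tfrac12 A_{dam_i, sire_i}} and off-diagonals are
#' \eqn{A_{ij} = \tfrac12 (A_{j, dam_i} + A_{j, sire_i})} for j preceding i.
#' Founders are assumed non-inbred and mutually unrelated; an unknown parent
#' contributes zero relationship.
#'
#' @param ped pedigree data frame; validated (and topologically ordered) with
#'   [validate_pedigree()] if not already.
#' @return A dense symmetric numeric matrix with dimnames equal to the ids in
#'   the topological order returned by [validate_pedigree()].
#' @examples
#' ped <- data.frame(id = c("d", "s", "o1", "o2"),
#'                   dam = c(NA, NA, "d", "d"), sire = c(NA, NA, "s", "s"))
#' A <- additive_relationship_matrix(ped)
#' A["o1", "o2"]  # full sibs: 0.5
#' @export
additive_relationship_matrix <- function(ped) {
  if (!inherits(ped, "pedigree_table")) ped <- validate_pedigree(ped)
  n <- nrow(ped)
  ids <- ped$id
  idx <- stats::setNames(seq_len(n), ids)
  dam_i <- unname(idx[ped$dam])
  sire_i <- unname(idx[ped$sire])
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    d <- dam_i[i]; s <- sire_i[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aj <- numeric(i - 1L)
      if (!is.na(d)) aj <- aj + A[j, d]
      if (!is.na(s)) aj <- aj + A[j, s]
      aj <- 0.5 * aj
      A[j, i] <- aj
      A[i, j] <- aj
    }
    A[i, i] <- 1 + if (!is.na(d) && !is.na(s)) 0.5 * A[d, s] else 0
  }
  A
}

#' Recursive kinship coefficient (test oracle)
#'
#' Computes the coefficient of kinship f(i, j) between two individuals by the
#' classical recursion, independently of the tabular relationship-matrix
#' construction: for i not an ancestor-ordered descendant the recursion
#' descends through the later-born individual's parents, with
#' \eqn{f(i, i) = \tfrac12 (1 + f(dam_i, sire_i))} and unknown parents
#' contributing zero. The additive relationship equals \code{2 * kinship}.
#'
#' @param ped pedigree (validated or raw).
#' @param i,j individual ids.
#' @return Kinship coefficient in [0, 1].
#' @export
kinship_coefficient <- function(ped, i, j) {
  if (!inherits(ped, "pedigree_table")) ped <- validate_pedigree(ped)
  ids <- ped$id
  if (!(i %in% ids)) stop("unknown id: ", i)
  if (!(j %in% ids)) stop("unknown id: ", j)
  pos <- stats::setNames(seq_along(ids), ids)
  dam <- stats::setNames(ped$dam, ids)
  sire <- stats::setNames(ped$sire, ids)
  memo <- new.env(parent = emptyenv())
  f <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    key <- if (pos[a] <= pos[b]) paste(a, b) else paste(b, a)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (a == b) {
      0.5 * (1 + f(dam[[a]], sire[[a]]))
    } else {
      # recurse through the individual appearing later in topological order,
      # which cannot be an ancestor of the other
      if (pos[a] < pos[b]) { tmp <- a; a <- b; b <- tmp }
      0.5 * (f(dam[[a]], b) + f(sire[[a]], b))
    }
    memo[[key]] <- val
    val
  }
  f(i, j)
}
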