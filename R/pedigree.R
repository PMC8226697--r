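#' Validate and topologically sort a pedigree
#'
#' Takes raw animal/sire/dam triples (any hashable ids; 0, "" or NA denote an
#' unknown parent), checks them, and returns a sorted pedigree in which every
#' parent precedes its offspring. Parents that only ever appear as parents are
#' appended as founder rows. Animals listed more than once, animals that are
#' their own parent, and pedigree cycles are errors.
#'
#' @param ped data.frame with columns \code{animal}, \code{sire}, \code{dam}
#'   (extra columns are dropped).
#' @return an object of class \code{pedigree_table}: a data.frame with columns
#'   \code{animal}, \code{sire}, \code{dam} (original ids), integer columns
#'   \code{animal_i}, \code{sire_i}, \code{dam_i} (position indices, 0 =
#'   unknown), and \code{F} (inbreeding coefficient, see [inbreeding()]).
#' @examples
#' ped_validate_sort(data.frame(animal = 3, sire = 1, dam = 2))
#' @export
ped_validate_sort <- function(ped) {
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  norm_id <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "" | x == "0"] <- NA_character_
    x
  }
  animal <- norm_id(ped$animal)
  sire <- norm_id(ped$sire)
  dam <- norm_id(ped$dam)
  if (anyNA(animal)) stop("missing animal id in pedigree")
  if (anyDuplicated(animal)) {
    stop("duplicate animal rows in pedigree: ",
         paste(utils::head(animal[duplicated(animal)], 3), collapse = ", "))
  }
  self <- which(animal == sire | animal == dam)
  if (length(self)) stop("animal is its own parent: ", animal[self[1]])

  # append parents never listed as animals, as founders
  parents <- unique(stats::na.omit(c(sire, dam)))
  extra <- setdiff(parents, animal)
  if (length(extra)) {
    animal <- c(animal, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam <- c(dam, rep(NA_character_, length(extra)))
  }
  n <- length(animal)
  idx <- seq_len(n)
  names(idx) <- animal
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam), 0L, idx[dam])

  # Kahn topological sort on parent -> offspring edges
  indeg <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) if (p > 0L) children[[p]] <- c(children[[p]], i)
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    stop("pedigree contains a cycle involving animal ",
         animal[setdiff(seq_len(n), order)[1]])
  }
  rank <- integer(n)
  rank[order] <- seq_len(n)
  new_idx <- function(old) c(0L, rank)[old + 1L]  # 0 stays unknown
  out <- data.frame(
    animal = animal[order], sire = sire[order], dam = dam[order],
    animal_i = seq_len(n),
    sire_i = new_idx(si[order]), dam_i = new_idx(di[order]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("pedigree_table", "data.frame")
  out$F <- inbreeding(out)
  out
}

#' Inbreeding coefficients by the Meuwissen-Luo recursion
#'
#' Computes the inbreeding coefficient of every animal in a sorted pedigree,
#' \eqn{F_i = a(s_i, d_i)/2}, without forming the dense relationship matrix.
#' Animals with at least one unknown parent get F = 0 (unknown parents are a
#' single non-inbred, unrelated base population).
#'
#' @param ped a \code{pedigree_table} from [ped_validate_sort()] (the F
#'   column, if present, is ignored and recomputed).
#' @return numeric vector of inbreeding coefficients in pedigree order.
#' @export
inbreeding <- function(ped) {
  si <- ped$sire_i; di <- ped$dam_i
  n <- length(si)
  F <- numeric(n)
  D <- numeric(n)  # Mendelian sampling variance scale a_ii contribution
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    Fs <- if (s > 0L) F[s] else 0
    Fd <- if (d > 0L) F[d] else 0
    D[i] <- if (s > 0L && d > 0L) 0.5 - 0.25 * (Fs + Fd)
            else if (s > 0L || d > 0L) 0.75 - 0.25 * (Fs + Fd)
            else 1
    if (s == 0L || d == 0L) { F[i] <- 0; next }
    # a_ii = sum_j L_ij^2 D_j accumulated by back-substitution from i
    v <- numeric(i)
    v[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (v[j] == 0) next
      aii <- aii + v[j]^2 * D[j]
      if (si[j] > 0L) v[si[j]] <- v[si[j]] + 0.5 * v[j]
      if (di[j] > 0L) v[di[j]] <- v[di[j]] + 0.5 * v[j]
    }
    F[i] <- aii - 1
  }
  F
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly from the pedigree by Henderson's rules, with
#' Mendelian-sampling variances \eqn{d_i = 1/2 - (F_s + F_d)/4} when both
#' parents are known (terms for unknown parents dropped). The animal-model
#' full conditionals of the Gibbs sampler consume this matrix; it never forms
#' A itself.
#'
#' @param ped a \code{pedigree_table}.
#' @param use_inbreeding logical; if FALSE, F is taken as 0 everywhere
#'   (textbook Henderson rules), otherwise the Meuwissen-Luo coefficients are
#'   used (default).
#' @return a sparse symmetric \code{\link[Matrix]{dsCMatrix}} of dimension
#'   n x n in pedigree order.
#' @examples
#' trio <- ped_validate_sort(data.frame(animal = 3, sire = 1, dam = 2))
#' a_inverse(trio)
#' @export
a_inverse <- function(ped, use_inbreeding = TRUE) {
  si <- ped$sire_i; di <- ped$dam_i
  n <- length(si)
  F <- if (use_inbreeding) ped$F else numeric(n)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii[[length(ii) + 1]] <<- i; jj[[length(jj) + 1]] <<- j
    xx[[length(xx) + 1]] <<- v
  }
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    Fs <- if (s > 0L) F[s] else 0
    Fd <- if (d > 0L) F[d] else 0
    dd <- if (s > 0L && d > 0L) 0.5 - 0.25 * (Fs + Fd)
          else if (s > 0L || d > 0L) 0.75 - 0.25 * (Fs + Fd)
          else 1
    al <- 1 / dd
    add(i, i, al)
    for (p in c(s, d)) {
      if (p > 0L) {
        add(min(i, p), max(i, p), -al / 2)
      }
    }
    known <- c(s, d)[c(s, d) > 0L]
    for (p in known) for (q in known) if (p <= q) add(p, q, al / 4)
  }
  # upper-triangle triplets; duplicates are summed by sparseMatrix
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                       symmetric = TRUE)
}

#' Dense numerator relationship matrix (tabular method)
#'
#' Test oracle: builds A by the tabular method,
#' \eqn{a_{ii} = 1 + F_i}, \eqn{a_{ij} = (a_{j,s_i} + a_{j,d_i})/2}. Refuses
#' pedigrees larger than \code{max_n} because the dense recursion is meant
#' for cross-checks, not production use.
#'
#' @param ped a \code{pedigree_table}.
#' @param max_n size cap (default 2000).
#' @return dense numeric n x n matrix.
#' @export
a_matrix_dense <- function(ped, max_n = 2000) {
  n <- nrow(ped)
  if (n > max_n) stop("pedigree larger than max_n = ", max_n,
                      "; a_matrix_dense is a small-pedigree oracle")
  si <- ped$sire_i; di <- ped$dam_i
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    asd <- if (s > 0L && d > 0L) A[s, d] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        v <- 0
        if (s > 0L) v <- v + 0.5 * A[j, s]
        if (d > 0L) v <- v + 0.5 * A[j, d]
        A[i, j] <- A[j, i] <- v
      }
    }
  }
  A
}

#' Export A-inverse in coordinate text format
#'
#' Writes the lower triangle of a sparse A-inverse as whitespace-separated
#' \code{i j value} rows for inspection or interchange.
#'
#' @param Ainv sparse symmetric matrix from [a_inverse()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_ainverse <- function(Ainv, path) {
  T <- as(as(Ainv, "generalMatrix"), "TsparseMatrix")
  keep <- T@i >= T@j
  df <- data.frame(i = T@i[keep] + 1L, j = T@j[keep] + 1L, value = T@x[keep])
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# parent columns as original ids with "0" for unknown (safe for 0 indices)
ped_parent_ids <- function(ped) {
  ids <- c("0", ped$animal)
  list(sire = ids[ped$sire_i + 1L], dam = ids[ped$dam_i + 1L])
}
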