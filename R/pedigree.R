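#' Read and validate a pedigree file
#'
#' Reads a comma- or tab-delimited pedigree with header `id,sire,dam,breed`,
#' where unknown parents are encoded as `0` or an empty string, validates it,
#' and returns it topologically sorted so that every parent precedes its
#' offspring.
#'
#' Breeds are `B` (sire line), `H` (dam line) and `BH` (two-way cross). A
#' `BH` animal with both parents known must have exactly one `B` and one `H`
#' parent; a parentage cycle is a hard error.
#'
#' @param path Path to the delimited pedigree file.
#' @param metafounder_map Named character vector mapping each pure breed to
#'   its metafounder label, used by [build_A_gamma()] when unknown parents
#'   are replaced by metafounders. Defaults to `c(B = "B", H = "H")`.
#' @return A tibble of class `cb_pedigree` with columns `id`, `sire`, `dam`
#'   (both `NA` when unknown) and `breed`, sorted parents-first.
#' @seealso [build_A()], [build_A_gamma()], [build_partial_A()]
#' @export
read_pedigree <- function(path, metafounder_map = c(B = "B", H = "H")) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", strip.white = TRUE)
  names(df) <- tolower(names(df))
  req <- c("id", "sire", "dam", "breed")
  if (!all(req %in% names(df))) {
    stop("pedigree file must have columns id, sire, dam, breed")
  }
  as_pedigree(df[req], metafounder_map = metafounder_map)
}

#' Coerce a data frame to a validated, sorted pedigree
#'
#' @param df Data frame with columns `id`, `sire`, `dam`, `breed`; unknown
#'   parents as `NA`, `"0"` or `""`.
#' @inheritParams read_pedigree
#' @return A `cb_pedigree` tibble, topologically sorted.
#' @export
as_pedigree <- function(df, metafounder_map = c(B = "B", H = "H")) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("id", "sire", "dam", "breed")) {
    df[[col]] <- as.character(df[[col]])
  }
  df$sire[df$sire %in% c("0", "", NA)] <- NA_character_
  df$dam[df$dam %in% c("0", "", NA)] <- NA_character_

  if (anyDuplicated(df$id)) {
    stop("duplicated animal ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  bad_breed <- setdiff(unique(df$breed), c("B", "H", "BH"))
  if (length(bad_breed)) {
    stop("unknown breed labels: ", paste(bad_breed, collapse = ", "))
  }
  missing_par <- setdiff(stats::na.omit(c(df$sire, df$dam)), df$id)
  if (length(missing_par)) {
    stop("parents referenced but absent from pedigree: ",
         paste(missing_par, collapse = ", "))
  }
  self_par <- df$id[!is.na(df$sire) & df$sire == df$id |
                    !is.na(df$dam) & df$dam == df$id]
  if (length(self_par)) {
    stop("animal is its own parent: ", paste(self_par, collapse = ", "))
  }

  # one B + one H parent for every fully-recorded crossbred
  pb <- function(p) ifelse(is.na(p), NA, df$breed[match(p, df$id)])
  sb <- pb(df$sire); db <- pb(df$dam)
  full_bh <- df$breed == "BH" & !is.na(sb) & !is.na(db)
  ok <- !full_bh | (sb != db & sb %in% c("B", "H") & db %in% c("B", "H"))
  if (any(!ok)) {
    stop("BH animal without one B and one H parent: ",
         paste(df$id[!ok], collapse = ", "))
  }

  df <- ped_topo_sort(df)
  out <- tibble::as_tibble(df)
  attr(out, "metafounder_map") <- metafounder_map
  class(out) <- c("cb_pedigree", class(out))
  out
}

# Kahn topological sort; errors with the offending ids on a cycle.
ped_topo_sort <- function(df) {
  n <- nrow(df)
  id <- df$id
  si <- match(df$sire, id)
  di <- match(df$dam, id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    stop("pedigree contains a parentage cycle involving: ",
         paste(id[setdiff(seq_len(n), order)], collapse = ", "))
  }
  df[order, , drop = FALSE]
}

#' Numerator relationship matrix by the tabular method
#'
#' Builds Wright's numerator relationship matrix `A` from a sorted pedigree:
#' `a_ii = 1 + F_i` with `F_i = a_sd / 2`, and
#' `a_ij = (a_js + a_jd) / 2` for `j` preceding `i`; unknown parents
#' contribute zero relationship.
#'
#' @param ped A `cb_pedigree` (see [as_pedigree()]).
#' @return A symmetric numeric matrix with animal ids as dimnames.
#' @export
build_A <- function(ped) {
  stopifnot(inherits(ped, "cb_pedigree"))
  tabular_A(ped$id, ped$sire, ped$dam)
}

# Core tabular recursion over pre-sorted ids; `init` optionally supplies
# leading pseudo-founder rows (metafounders) with their own relationships.
tabular_A <- function(id, sire, dam, init = NULL) {
  pre <- if (is.null(init)) character(0) else rownames(init)
  all_id <- c(pre, id)
  n <- length(all_id)
  A <- matrix(0, n, n, dimnames = list(all_id, all_id))
  k0 <- length(pre)
  if (k0) A[seq_len(k0), seq_len(k0)] <- init
  si <- match(sire, all_id)
  di <- match(dam, all_id)
  for (r in seq_along(id)) {
    i <- k0 + r
    s <- si[r]; d <- di[r]
    prev <- seq_len(i - 1L)
    rel <- numeric(i - 1L)
    if (!is.na(s)) rel <- rel + A[prev, s]
    if (!is.na(d)) rel <- rel + A[prev, d]
    rel <- rel / 2
    A[prev, i] <- rel
    A[i, prev] <- rel
    f <- if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0
    A[i, i] <- 1 + f
  }
  A
}

#' Pedigree relationship matrix with metafounders
#'
#' Builds the metafounder numerator relationship matrix `A^Gamma`: unknown
#' parents are replaced by pseudo-founders (one per pure breed) whose
#' self- and cross-relationships are given by the 2x2 `Gamma` matrix, and the
#' tabular recursion then runs unchanged. With `Gamma = 0` the result equals
#' [build_A()] exactly. Diagonals of `A^Gamma` may exceed the classical
#' `1 + F` bound because `Gamma` entries themselves may exceed 1.
#'
#' Unknown parents of purebreds map to their own breed's metafounder; for a
#' crossbred with one known parent the missing parent maps to the other
#' breed, and for a crossbred with no known parents the sire slot maps to
#' `B` and the dam slot to `H` (the two-way production system's structure).
#'
#' @inheritParams build_A
#' @param gamma A [gamma_matrix()] (entries `gamma_B`, `gamma_BH`, `gamma_H`).
#' @param keep_metafounders Keep the two metafounder rows/columns (labelled
#'   `MF_B`, `MF_H`) in the returned matrix? They are needed for
#'   metafounder-contrast reliabilities; default drops them.
#' @return A symmetric matrix over animal ids (plus metafounder labels when
#'   `keep_metafounders = TRUE`).
#' @export
build_A_gamma <- function(ped, gamma, keep_metafounders = FALSE) {
  stopifnot(inherits(ped, "cb_pedigree"))
  gamma <- as_gamma(gamma)
  mf_of <- resolve_metafounders(ped)
  G0 <- matrix(c(gamma$gamma_B, gamma$gamma_BH,
                 gamma$gamma_BH, gamma$gamma_H), 2, 2,
               dimnames = list(c("MF_B", "MF_H"), c("MF_B", "MF_H")))
  A <- tabular_A(ped$id, mf_of$sire, mf_of$dam, init = G0)
  if (!keep_metafounders) {
    A <- A[ped$id, ped$id, drop = FALSE]
  }
  A
}

# Replace unknown parents by metafounder labels MF_B / MF_H.
resolve_metafounders <- function(ped) {
  sire <- ped$sire
  dam <- ped$dam
  for (i in seq_len(nrow(ped))) {
    b <- ped$breed[i]
    s_na <- is.na(sire[i]); d_na <- is.na(dam[i])
    if (!s_na && !d_na) next
    if (b %in% c("B", "H")) {
      lab <- paste0("MF_", b)
      if (s_na) sire[i] <- lab
      if (d_na) dam[i] <- lab
    } else {
      if (s_na && d_na) {
        sire[i] <- "MF_B"; dam[i] <- "MF_H"
      } else if (s_na) {
        kb <- ped$breed[match(dam[i], ped$id)]
        if (is.na(kb) || kb == "BH") stop("cannot infer metafounder for ", ped$id[i])
        sire[i] <- paste0("MF_", setdiff(c("B", "H"), kb))
      } else {
        kb <- ped$breed[match(sire[i], ped$id)]
        if (is.na(kb) || kb == "BH") stop("cannot infer metafounder for ", ped$id[i])
        dam[i] <- paste0("MF_", setdiff(c("B", "H"), kb))
      }
    }
  }
  list(sire = sire, dam = dam)
}

#' Breed-specific partial relationship matrices
#'
#' Splits the numerator relationship matrix into breed-of-origin partial
#' matrices by the Garcia-Cortes and Toro recursion. A founder of breed `b`
#' has partial self-relationship 1 for `b` and 0 for the other breed;
#' thereafter `a^(b)_ii = f^(b)_i + a^(b)_sd / 2`, where `f^(b)_i` is the
#' expected fraction of the genome originating from breed `b`, and
#' off-diagonals follow the usual parent-average rule. The two partial
#' matrices sum to `A` elementwise.
#'
#' @inheritParams build_A
#' @return A named list with symmetric matrices `B` and `H`.
#' @export
build_partial_A <- function(ped) {
  stopifnot(inherits(ped, "cb_pedigree"))
  id <- ped$id
  n <- length(id)
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)

  # expected breed-B genome fraction
  fB <- numeric(n)
  for (i in seq_len(n)) {
    if (is.na(si[i]) && is.na(di[i])) {
      fB[i] <- switch(ped$breed[i], B = 1, H = 0,
                      BH = stop("BH animal ", id[i],
                                " has no known parent; breed fractions ",
                                "are undefined for partial matrices"))
    } else if (is.na(si[i]) || is.na(di[i])) {
      known <- if (is.na(si[i])) fB[di[i]] else fB[si[i]]
      miss <- switch(ped$breed[i],
                     B = 1, H = 0,
                     # F1: the unrecorded parent is purebred of the other breed
                     BH = if (known >= 0.5) 0 else 1)
      fB[i] <- (known + miss) / 2
    } else {
      fB[i] <- (fB[si[i]] + fB[di[i]]) / 2
    }
  }

  part <- function(f) {
    A <- matrix(0, n, n, dimnames = list(id, id))
    for (i in seq_len(n)) {
      s <- si[i]; d <- di[i]
      prev <- seq_len(i - 1L)
      if (i > 1L) {
        rel <- numeric(i - 1L)
        if (!is.na(s)) rel <- rel + A[prev, s]
        if (!is.na(d)) rel <- rel + A[prev, d]
        rel <- rel / 2
        A[prev, i] <- rel
        A[i, prev] <- rel
      }
      cross <- if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0
      A[i, i] <- f[i] + cross
    }
    A
  }
  list(B = part(fB), H = part(1 - fB))
}

#' Pedigree inbreeding coefficients
#'
#' `F_i = a_ii - 1` from the numerator relationship matrix.
#'
#' @inheritParams build_A
#' @return A tibble with columns `id` and `F`.
#' @export
inbreeding <- function(ped) {
  A <- build_A(ped)
  tibble::tibble(id = ped$id, F = unname(diag(A)) - 1)
}

#' Metafounder relationship matrix
#'
#' Container for the 2x2 within- and across-breed ancestral relationship
#' matrix Gamma. Warns (does not fail) when the off-diagonal exceeds the
#' geometric mean of the diagonals, i.e. when Gamma is not positive
#' semi-definite.
#'
#' @param gamma_B,gamma_H Within-breed metafounder self-relationships.
#' @param gamma_BH Across-breed metafounder relationship.
#' @return An object of class `cb_gamma` (a named list).
#' @export
gamma_matrix <- function(gamma_B, gamma_BH, gamma_H) {
  stopifnot(is.numeric(gamma_B), is.numeric(gamma_BH), is.numeric(gamma_H))
  if (gamma_BH^2 > gamma_B * gamma_H + 1e-12) {
    warning("gamma_BH^2 > gamma_B * gamma_H: Gamma is not positive semi-definite")
  }
  structure(list(gamma_B = gamma_B, gamma_BH = gamma_BH, gamma_H = gamma_H),
            class = "cb_gamma")
}

as_gamma <- function(x) {
  if (inherits(x, "cb_gamma")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(gamma_matrix(x, x, x))
  if (is.matrix(x) && all(dim(x) == 2L)) {
    return(gamma_matrix(x[1, 1], x[1, 2], x[2, 2]))
  }
  stop("cannot interpret 'gamma'; use gamma_matrix()")
}

#' @export
as.matrix.cb_gamma <- function(x, ...) {
  matrix(c(x$gamma_B, x$gamma_BH, x$gamma_BH, x$gamma_H), 2, 2,
         dimnames = list(c("B", "H"), c("B", "H")))
}

#' @export
print.cb_gamma <- function(x, ...) {
  cat("Metafounder relationship matrix (Gamma)\n")
  print(round(as.matrix(x), 4))
  invisible(x)
}

#' Write / read a relationship matrix in long format
#'
#' Lower triangle (including the diagonal) as gzip-compressed
#' `id_i<TAB>id_j<TAB>value`.
#'
#' @param A Labeled symmetric matrix.
#' @param path Output path (a `.gz` suffix is honoured).
#' @return `write_relmat()` returns `path` invisibly; `read_relmat()`
#'   returns the symmetric matrix.
#' @export
write_relmat <- function(A, path) {
  stopifnot(is.matrix(A), !is.null(rownames(A)))
  idx <- which(lower.tri(A, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(id_i = rownames(A)[idx[, 1]],
                   id_j = colnames(A)[idx[, 2]],
                   value = A[idx])
  con <- gzfile(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_relmat
#' @export
read_relmat <- function(path) {
  df <- utils::read.table(gzfile(path), header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "numeric"))
  ids <- unique(c(df$id_i, df$id_j))
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  A[cbind(df$id_i, df$id_j)] <- df$value
  A[cbind(df$id_j, df$id_i)] <- df$value
  A
}
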