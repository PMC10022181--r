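#' Breed-of-origin tracing against a genotyped parent
#'
#' For one crossbred chromosome, compares each of its two phased haplotypes
#' with each of the genotyped parent's two haplotypes (four comparisons),
#' counting allele differences. The crossbred haplotype in the pair with the
#' smallest count is assigned the parent's breed; the other haplotype gets
#' the other breed (the F1 constraint).
#'
#' Ties between the two crossbred haplotypes' best counts are resolved by
#' their second-smallest counts; if still tied, haplotype 1 takes the
#' parent's breed and the assignment is flagged.
#'
#' @param cross_h1,cross_h2 Integer vectors (0/1), the crossbred haplotypes
#'   on one chromosome.
#' @param parent_h1,parent_h2 The parent's haplotypes, same markers/order.
#' @param parent_breed `"B"` or `"H"`.
#' @return A list: `breed` (length-2 character, breeds of haplotypes 1 and 2),
#'   `counts` (named 4-vector of difference counts), `tie` (logical),
#'   `score` (margin between the two haplotypes' best counts).
#' @export
trace_with_parent <- function(cross_h1, cross_h2, parent_h1, parent_h2,
                              parent_breed) {
  stopifnot(parent_breed %in% c("B", "H"))
  lens <- lengths(list(cross_h1, cross_h2, parent_h1, parent_h2))
  if (length(unique(lens)) != 1L) stop("haplotype lengths differ")
  d <- c(h1p1 = sum(cross_h1 != parent_h1, na.rm = TRUE),
         h1p2 = sum(cross_h1 != parent_h2, na.rm = TRUE),
         h2p1 = sum(cross_h2 != parent_h1, na.rm = TRUE),
         h2p2 = sum(cross_h2 != parent_h2, na.rm = TRUE))
  best1 <- min(d["h1p1"], d["h1p2"])
  best2 <- min(d["h2p1"], d["h2p2"])
  other <- setdiff(c("B", "H"), parent_breed)
  tie <- FALSE
  if (best1 < best2) {
    hap_from_parent <- 1L
  } else if (best2 < best1) {
    hap_from_parent <- 2L
  } else {
    sec1 <- max(d["h1p1"], d["h1p2"])
    sec2 <- max(d["h2p1"], d["h2p2"])
    tie <- TRUE
    hap_from_parent <- if (sec1 < sec2) 1L else if (sec2 < sec1) 2L else 1L
  }
  breed <- if (hap_from_parent == 1L) c(parent_breed, other) else c(other, parent_breed)
  list(breed = breed, counts = d, tie = tie,
       score = abs(as.numeric(best2) - as.numeric(best1)))
}

#' Breed-of-origin tracing against purebred reference panels
#'
#' Splits one crossbred chromosome into non-overlapping windows of `window`
#' consecutive SNPs (the final window may be shorter). For each crossbred
#' haplotype segment, the number of exact copies among each breed panel's
#' corresponding segments is counted; the segment votes for the breed with
#' the larger copy count (abstaining, flagged, when neither panel carries a
#' copy). Each haplotype is assigned the breed winning the majority of its
#' segment votes, and the F1 constraint forces complementary breeds on the
#' two haplotypes: if both majorities agree, the haplotype with the larger
#' total copy count for that breed keeps it and the conflict is flagged.
#'
#' @param cross_h1,cross_h2 Crossbred haplotypes (0/1 vectors) on one
#'   chromosome.
#' @param panel_B,panel_H Matrices of reference haplotypes (rows) for each
#'   breed over the same markers.
#' @param window Window length in SNPs (default 50).
#' @return A list: `breed` (length-2), `votes` (2 x 2 matrix of window votes
#'   by haplotype and breed), `abstained` (windows without any copy),
#'   `conflict` (logical), `score` (vote margin for haplotype 1).
#' @export
trace_with_panel <- function(cross_h1, cross_h2, panel_B, panel_H, window = 50L) {
  stopifnot(window >= 1L, nrow(panel_B) >= 1L, nrow(panel_H) >= 1L)
  m <- length(cross_h1)
  stopifnot(length(cross_h2) == m, ncol(panel_B) == m, ncol(panel_H) == m)
  starts <- seq(1L, m, by = window)
  votes <- matrix(0L, 2, 2, dimnames = list(c("h1", "h2"), c("B", "H")))
  copies <- matrix(0L, 2, 2, dimnames = list(c("h1", "h2"), c("B", "H")))
  abstained <- integer(0)
  for (w in seq_along(starts)) {
    idx <- starts[w]:min(starts[w] + window - 1L, m)
    for (h in 1:2) {
      seg <- if (h == 1L) cross_h1[idx] else cross_h2[idx]
      nB <- sum(colSums(t(panel_B[, idx, drop = FALSE]) != seg) == 0L)
      nH <- sum(colSums(t(panel_H[, idx, drop = FALSE]) != seg) == 0L)
      copies[h, ] <- copies[h, ] + c(nB, nH)
      if (nB == 0L && nH == 0L) {
        if (h == 1L) abstained <- c(abstained, w)
      } else if (nB > nH) {
        votes[h, "B"] <- votes[h, "B"] + 1L
      } else if (nH > nB) {
        votes[h, "H"] <- votes[h, "H"] + 1L
      }
    }
  }
  maj <- function(h) {
    if (votes[h, "B"] > votes[h, "H"]) "B"
    else if (votes[h, "H"] > votes[h, "B"]) "H"
    else c("B", "H")[which.max(copies[h, ])]
  }
  m1 <- maj(1); m2 <- maj(2)
  conflict <- FALSE
  if (m1 != m2) {
    breed <- c(m1, m2)
  } else {
    # both haplotypes favour the same breed: F1 constraint decides by the
    # larger total copy count for the contested breed
    conflict <- TRUE
    other <- setdiff(c("B", "H"), m1)
    breed <- if (copies[1, m1] >= copies[2, m1]) c(m1, other) else c(other, m1)
  }
  list(breed = breed, votes = votes, abstained = abstained,
       conflict = conflict,
       score = abs(votes[1, "B"] - votes[1, "H"]))
}

#' Trace breed of origin for all genotyped crossbreds
#'
#' Dispatches per crossbred and per chromosome: when a genotyped, phased
#' parent exists the parent-comparison rule is used (sire preferred when
#' both parents are genotyped); otherwise the reference-panel rule with all
#' phased purebreds of each breed. Crossbreds without phased haplotypes are
#' excluded and reported.
#'
#' @param gs A [genotype_set()] with haplotypes.
#' @param ped A `cb_pedigree` covering the crossbreds.
#' @param window Panel-rule window length in SNPs.
#' @return An object of class `cb_boa`: a tibble with one row per crossbred
#'   chromosome and haplotype (`id`, `chr`, `hap`, `breed`, `rule`,
#'   `score`, `flagged`), plus attribute `excluded` (unphased crossbreds).
#' @export
trace_all <- function(gs, ped, window = 50L) {
  stopifnot(inherits(ped, "cb_pedigree"))
  ph <- phased_ids(gs)
  cross <- intersect(rownames(gs$dosage)[gs$breed == "BH"], rownames(gs$dosage))
  excluded <- setdiff(cross, ph)
  cross <- intersect(cross, ph)
  chrs <- unique(gs$map$chr)
  chr_idx <- lapply(chrs, function(ch) which(gs$map$chr == ch))
  names(chr_idx) <- chrs

  panels <- lapply(c(B = "B", H = "H"), function(b) {
    ids <- intersect(ph, names(gs$breed)[gs$breed == b])
    if (!length(ids)) return(NULL)
    rbind(gs$hap1[ids, , drop = FALSE], gs$hap2[ids, , drop = FALSE])
  })

  rows <- vector("list", length(cross))
  for (k in seq_along(cross)) {
    i <- cross[k]
    prow <- match(i, ped$id)
    par <- NULL; par_breed <- NULL
    if (!is.na(prow)) {
      s <- ped$sire[prow]; d <- ped$dam[prow]
      if (!is.na(s) && s %in% ph) {
        par <- s
      } else if (!is.na(d) && d %in% ph) {
        par <- d
      }
      if (!is.null(par)) par_breed <- gs$breed[par]
    }
    out_chr <- lapply(chrs, function(ch) {
      idx <- chr_idx[[ch]]
      h1 <- gs$hap1[i, idx]; h2 <- gs$hap2[i, idx]
      if (!is.null(par)) {
        r <- trace_with_parent(h1, h2, gs$hap1[par, idx], gs$hap2[par, idx],
                               par_breed)
        tibble::tibble(id = i, chr = ch, hap = 1:2, breed = r$breed,
                       rule = "parent", score = r$score, flagged = r$tie)
      } else {
        if (is.null(panels$B) || is.null(panels$H)) {
          stop("no phased purebred panel available for crossbred ", i)
        }
        r <- trace_with_panel(h1, h2, panels$B[, idx, drop = FALSE],
                              panels$H[, idx, drop = FALSE], window = window)
        tibble::tibble(id = i, chr = ch, hap = 1:2, breed = r$breed,
                       rule = "panel", score = r$score,
                       flagged = r$conflict || length(r$abstained) > 0)
      }
    })
    rows[[k]] <- dplyr::bind_rows(out_chr)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "excluded") <- excluded
  class(out) <- c("cb_boa", class(out))
  out
}

#' Breed-specific allele contents
#'
#' From a breed-of-origin assignment, builds the allele-content matrices used
#' by the breed-specific genomic relationship matrices: `Q_B`/`Q_H` hold, per
#' crossbred and marker, the allele (0/1) carried on the haplotype assigned
#' to each breed, and `M_B`/`M_H` hold purebred dosages by breed. By
#' construction `Q_B + Q_H` equals the crossbred dosage at every non-missing
#' marker.
#'
#' @param gs A [genotype_set()] with haplotypes.
#' @param boa A `cb_boa` from [trace_all()].
#' @return A list of class `cb_allele_content` with matrices `Q_B`, `Q_H`,
#'   `M_B`, `M_H`.
#' @export
build_allele_content <- function(gs, boa) {
  cross <- unique(boa$id)
  mk <- colnames(gs$dosage)
  QB <- matrix(NA_integer_, length(cross), length(mk),
               dimnames = list(cross, mk))
  QH <- QB
  for (i in cross) {
    rows_i <- boa[boa$id == i, ]
    for (ch in unique(rows_i$chr)) {
      idx <- which(gs$map$chr == ch)
      sub <- rows_i[rows_i$chr == ch, ]
      b_of_hap <- sub$breed[order(sub$hap)]
      h <- list(gs$hap1[i, idx], gs$hap2[i, idx])
      QB[i, idx] <- h[[which(b_of_hap == "B")]]
      QH[i, idx] <- h[[which(b_of_hap == "H")]]
    }
  }
  # missing haplotype alleles: drop the marker for that individual in both
  both_na <- is.na(QB) | is.na(QH)
  QB[both_na] <- NA_integer_
  QH[both_na] <- NA_integer_

  pure <- lapply(c(B = "B", H = "H"), function(b) {
    ids <- rownames(gs$dosage)[gs$breed == b]
    gs$dosage[ids, , drop = FALSE]
  })
  structure(list(Q_B = QB, Q_H = QH, M_B = pure$B, M_H = pure$H),
            class = "cb_allele_content")
}

#' Accuracy of breed-of-origin assignments against known truth
#'
#' @param boa A `cb_boa`.
#' @param truth Tibble with columns `id`, `chr`, `hap`, `breed` (true
#'   origins, as produced by the simulator).
#' @return Fraction of haplotype-chromosomes assigned to their true breed.
#' @export
boa_accuracy <- function(boa, truth) {
  merged <- dplyr::inner_join(
    tibble::as_tibble(boa)[c("id", "chr", "hap", "breed")],
    dplyr::rename(tibble::as_tibble(truth), true_breed = "breed"),
    by = c("id", "chr", "hap"))
  if (!nrow(merged)) stop("no overlap between assignments and truth")
  mean(merged$breed == merged$true_breed)
}

#' Write breed-of-origin assignments as TSV
#'
#' Columns: `individual`, `chromosome`, `hap_index`, `breed`, `score`.
#'
#' @param boa A `cb_boa`.
#' @param path Output path.
#' @export
write_boa <- function(boa, path) {
  df <- data.frame(individual = boa$id, chromosome = boa$chr,
                   hap_index = boa$hap, breed = boa$breed, score = boa$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
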