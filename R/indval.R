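## Dufrene-Legendre indicator species analysis (IndVal) with a
## group-label permutation test.

#' Indicator value (IndVal) of every species for every habitat
#'
#' For species \code{s} and habitat \code{j}: specificity
#' \code{A_sj} = (mean abundance of \code{s} in plots of \code{j}) /
#' (sum over habitats of the mean abundance of \code{s}); fidelity
#' \code{B_sj} = fraction of the plots of \code{j} containing \code{s};
#' \code{IndVal_sj = A_sj * B_sj} on the 0-1 scale, so a species occurring
#' in every plot of one habitat and absent elsewhere scores exactly 1.
#' A species' indicator value is its maximum over habitats.
#'
#' @param comm plots x species abundance matrix.
#' @param habitats named character vector (or factor), plot -> habitat.
#' @return list with \code{A}, \code{B}, \code{indval} (species x habitat
#'   matrices; species with zero total abundance get \code{NA} rows) and a
#'   per-species data.frame \code{species} with \code{indval} (the maximum)
#'   and \code{best_habitat}.
#' @export
indval <- function(comm, habitats) {
  stopIfNot2(all(rownames(comm) %in% names(habitats)),
             "every plot needs a habitat label")
  g <- factor(as.character(habitats[rownames(comm)]))
  stopIfNot2(nlevels(g) >= 2L, "need >= 2 habitats")
  nPer <- table(g)
  stopIfNot2(all(nPer >= 1L), "empty habitat")

  meanAb <- rowsum(comm, g) / as.vector(nPer)          # habitat x species
  occFrac <- rowsum((comm > 0) + 0, g) / as.vector(nPer)
  tot <- colSums(meanAb)
  A <- t(sweep(meanAb, 2L, tot, "/"))                  # species x habitat
  B <- t(occFrac)
  zero <- tot == 0
  A[zero, ] <- NA_real_
  iv <- A * B
  best <- apply(iv, 1L, function(v) if (all(is.na(v))) NA_integer_ else
    which.max(v))
  species <- data.frame(
    species = rownames(iv),
    indval = apply(iv, 1L, function(v) if (all(is.na(v))) NA_real_ else max(v)),
    best_habitat = colnames(iv)[ifelse(is.na(best), 1L, best)],
    row.names = NULL
  )
  species$best_habitat[is.na(best)] <- NA_character_
  list(A = A, B = B, indval = iv, species = species)
}

#' IndVal permutation test
#'
#' Significance of each species' (maximum-habitat) indicator value, from
#' permuting the plot-to-habitat labels (group sizes preserved):
#' \code{p = (1 + #\{IndVal_perm >= IndVal_obs\}) / (n_perm + 1)}.  Species
#' with zero total abundance are excluded from testing.
#'
#' @inheritParams indval
#' @param n_perm number of label permutations (>= 99).
#' @param seed integer seed.
#' @param p_adjust \code{"none"} (default, raw permutation p) or
#'   \code{"holm"}.
#' @return the [indval()] list with columns \code{p_value} and \code{n_perm}
#'   added to \code{$species}.
#' @export
indvalTest <- function(comm, habitats, n_perm = 999L, seed = 1L,
                       p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  stopIfNot2(n_perm >= 99, "n_perm must be >= 99")
  obs <- indval(comm, habitats)
  g <- as.character(habitats[rownames(comm)])
  maxObs <- obs$species$indval
  count <- integer(length(maxObs))
  withSeed(seed, {
    for (i in seq_len(n_perm)) {
      gp <- stats::setNames(sample(g), rownames(comm))
      ivp <- indval(comm, gp)$species$indval
      count <- count + (!is.na(ivp) & !is.na(maxObs) &
                          ivp >= maxObs - 1e-12)
    }
  })
  p <- (1 + count) / (n_perm + 1)
  p[is.na(maxObs)] <- NA_real_
  if (p_adjust == "holm") p <- stats::p.adjust(p, method = "holm")
  obs$species$p_value <- p
  obs$species$n_perm <- n_perm
  obs
}
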