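# Shared fixtures, built in code.

toyTree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

toyD <- function() patristicDistances(toyTree())

# A 20-plot, 4-habitat toy community with a perfect indicator species: sp1
# occurs (abundance 1) in every plot of H1 and nowhere else; the remaining
# species are filled deterministically.
perfectIndicatorFixture <- function(n_habitats = 4, plots_per_habitat = 5) {
  n <- n_habitats * plots_per_habitat
  habitats <- stats::setNames(rep(paste0("H", seq_len(n_habitats)),
                                  each = plots_per_habitat),
                              sprintf("P%02d", seq_len(n)))
  comm <- matrix(0, n, 4,
                 dimnames = list(names(habitats), paste0("sp", 1:4)))
  comm[habitats == "H1", "sp1"] <- 1
  comm[, "sp2"] <- 1                       # ubiquitous
  comm[seq(1, n, by = 2), "sp3"] <- 2      # habitat-independent
  comm[habitats %in% c("H2", "H3"), "sp4"] <- 3
  list(comm = comm, habitats = habitats)
}

# Environment table with composition step-changing habitats.
gradientEnv <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    plot = sprintf("P%03d", seq_len(n)),
    elevation = runif(n, 1200, 2200),
    latitude = runif(n, 36.6, 36.9),
    longitude = runif(n, 59.2, 59.5)
  )
}
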