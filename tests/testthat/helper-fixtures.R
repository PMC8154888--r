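# shared fixtures: small mating designs, an independent recursive-kinship
# oracle, random pedigree generators and balanced half-sib data

small_config <- function(seed = 1, k1 = list(mean = 10, sigma_a2 = 4,
                                             sigma_c2 = 1, sigma_e2 = 5,
                                             test_day = TRUE),
                         extra_traits = NULL, ...) {
  traits <- c(list(y1 = k1), extra_traits)
  sim_config(traits = traits,
             n_sires = 8, n_dams = 12,
             mates_per_sire = c(2, 2, 2, 2, 1, 1, 1, 1),
             offspring_per_family = 6, fish_per_day = 12,
             seed = seed, ...)
}

# kinship by recursion with memoisation, independent of the tabular method
oracle_kinship <- function(ped) {
  n <- nrow(ped)
  si <- ped$sire_idx
  di <- ped$dam_idx
  phi <- matrix(NA_real_, n, n)
  k <- function(i, j) {
    if (!is.na(phi[i, j])) return(phi[i, j])
    val <- if (i == j) {
      0.5 * (1 + if (!is.na(si[i]) && !is.na(di[i])) k(si[i], di[i]) else 0)
    } else {
      a <- max(i, j); b <- min(i, j)  # a is younger (later in order)
      v <- 0
      if (!is.na(si[a])) v <- v + 0.5 * k(si[a], b)
      if (!is.na(di[a])) v <- v + 0.5 * k(di[a], b)
      v
    }
    phi[i, j] <<- val; phi[j, i] <<- val
    val
  }
  for (i in seq_len(n)) for (j in seq_len(i)) k(i, j)
  phi
}

# random valid pedigree: founders plus descendants with parents drawn from
# earlier animals (or unknown)
random_pedigree <- function(n = 20, n_founders = 6, seed = 1) {
  set.seed(seed)
  animal <- sprintf("A%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    pool <- seq_len(i - 1L)
    pick <- sample(pool, min(2L, length(pool)))
    if (stats::runif(1) < 0.9) sire[i] <- animal[pick[1L]]
    if (length(pick) > 1L && stats::runif(1) < 0.9)
      dam[i] <- animal[pick[2L]]
  }
  pedigree(animal, sire, dam)
}

# balanced paternal half-sib design: s unrelated sires, nper offspring each
# (dams unknown), phenotypes by direct composition
half_sib_data <- function(s = 30, nper = 12, sa2 = 6, se2 = 10, mu = 20,
                          seed = 1) {
  set.seed(seed)
  sires <- sprintf("S%02d", seq_len(s))
  off <- sprintf("O%04d", seq_len(s * nper))
  ped <- pedigree(c(sires, off), c(rep(NA, s), rep(sires, each = nper)), NA)
  a_sire <- stats::rnorm(s, sd = sqrt(sa2))
  y <- mu + rep(a_sire / 2, each = nper) +
    stats::rnorm(s * nper, sd = sqrt(se2 + 0.75 * sa2))
  list(ped = ped,
       phen = data.frame(fish_id = off, y = y,
                         sire_group = rep(seq_len(s), each = nper)))
}

# closed-form ANOVA-REML estimators for the balanced half-sib design
half_sib_anova <- function(phen, nper) {
  msb <- nper * stats::var(tapply(phen$y, phen$sire_group, mean))
  msw <- mean(tapply(phen$y, phen$sire_group, var))
  sa2 <- 4 * (msb - msw) / nper
  list(sigma_a2 = sa2, sigma_e2 = msw - 0.75 * sa2)
}

write_ped_file <- function(ped, path, header = TRUE, sep = ",") {
  df <- as.data.frame(ped)[, c("animal", "sire", "dam")]
  df$sire[is.na(df$sire)] <- "0"
  df$dam[is.na(df$dam)] <- "0"
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = header, quote = FALSE)
  path
}
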