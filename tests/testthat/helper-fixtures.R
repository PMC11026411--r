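# Fixtures are built in code; nothing is read from disk unless a test writes
# its own temporary file first.

# Minimal raw trait table in Amniote column layout.
make_raw_traits <- function() {
  data.frame(
    species = c("Vulpes vulpes", "Rattus rattus", "Macropus rufus",
                "Sorex araneus", "Loxodonta africana"),
    subclass = c("Eutheria", "Eutheria", "Metatheria", "Eutheria", "Eutheria"),
    order = c("Carnivora", "Rodentia", "Diprotodontia", "Soricomorpha",
              "Proboscidea"),
    adult_body_mass_g = c(5000, 300, 35000, 8, 4e6),
    female_body_mass_g = c(4800, NA, 26000, NA, 3.2e6),
    male_body_mass_g = c(5500, NA, 55000, NA, 5e6),
    weaning_weight_g = c(700, 40, 4000, 2.5, 5.5e5),
    litter_or_clutch_size_n = c(4.5, 6, 1, 5.5, 1),
    gestation_d = c(52, 22, 33, 24, 660),
    weaning_d = c(56, 25, 360, 25, 1500),
    check.names = FALSE, stringsAsFactors = FALSE)
}

# Small deterministic analysis table around a known line.
make_line_table <- function(n = 40, seed = 1, a = -0.2, b = 0.78,
                            c = NA, sd = 0.2) {
  set.seed(seed)
  x <- runif(n, 0.5, 8.5)
  z <- 1.5 + 0.25 * x + rnorm(n, 0, 0.1)
  y <- a + b * x + rnorm(n, 0, sd)
  if (!is.na(c)) y <- y + c * z
  data.frame(species = sprintf("sp%03d", seq_len(n)), y = y, x = x, z = z,
             stringsAsFactors = FALSE)
}

# Direct multivariate-normal log-density oracle (explicit inverse).
mvn_loglik_oracle <- function(e, V) {
  n <- length(e)
  as.numeric(-0.5 * (n * log(2 * pi) + determinant(V, logarithm = TRUE)$modulus +
                       t(e) %*% solve(V) %*% e))
}
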