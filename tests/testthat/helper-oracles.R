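# Independent oracles used across the suite. These deliberately take a
# different route from the package implementation they check.

# receptor-noise chromatic distance as the noise-weighted projection:
# minimise over an achromatic shift c of sum_i (df_i - c)^2 / e_i^2
# (weighted-variance identity), independent of the closed forms.
rnl_projection_oracle <- function(df, e) {
  w <- 1 / e^2
  c0 <- sum(w * df) / sum(w)
  sqrt(sum(w * (df - c0)^2))
}

# all permutations of 1..n (n small), for exhaustive permutation p-values
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# exhaustive two-sided permutation p-value for a Pearson correlation
permutation_p <- function(x, y) {
  r_obs <- abs(stats::cor(x, y))
  P <- all_perms(length(y))
  rs <- apply(P, 1, function(idx) abs(stats::cor(x, y[idx])))
  mean(rs >= r_obs - 1e-12)
}

# closed-form reflectance of the quarter-wave stack (H L)^N H between
# index-1 media at the tuning wavelength
quarter_wave_R <- function(nH, nL, N) {
  Y <- (nH / nL)^(2 * N) * nH^2
  ((1 - Y) / (1 + Y))^2
}

# Gaussian spectrum parameters spanning the observed descriptor ranges
table1_range_grid <- function() {
  expand.grid(peak = c(350, 423, 500), fwhm = c(70, 85, 95),
              amp = c(1, 15, 35))
}

# frozen regression orderings for the fixed synthetic fixtures (computed
# once from the fixtures at their stated seeds, then frozen; they are
# regression values for these fixtures, not biological claims)
frozen_uv_ranking <- function()
  c("heli_III", "heli_I", "heli_IV", "heli_II", "avian_vs")

frozen_comimic_ranking <- function()
  c("heli_III", "heli_I", "heli_IV", "heli_II", "avian_vs")

# two 4-individual groups of synthetic wing spectra from stacks whose
# period differs by 8 nm -- the desk-scale co-mimic comparison fixture
comimic_groups <- function() {
  stack_a <- sara_ridge_stack()
  stack_b <- multilayer_stack(list(layer(1.0, 115), layer(1.56, 81)))
  gen_group <- function(stack, seeds, taxon) {
    base <- reflectance_spectrum(stack, 300:700, 0, taxon = taxon)
    scale <- 30.6 / max(base$reflectance_pct)
    lapply(seeds, function(sd) {
      set.seed(sd)
      y <- pmax(base$reflectance_pct * scale +
                  stats::rnorm(401, 0, 0.5), 0)
      wing_spectrum(300:700, y, taxon = taxon,
                    individual = paste0("i", sd))
    })
  }
  list(A = gen_group(stack_a, 101:104, "mimic_a"),
       B = gen_group(stack_b, 201:204, "mimic_b"))
}
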