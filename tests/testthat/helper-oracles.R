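# Shared fixtures and independent oracles for the suite.

.test_cache <- new.env()

# The default parent closure and the packaged fixture are used by many
# tests; compute/load them once per run.
cached_closure <- function() {
  if (is.null(.test_cache$closure)) {
    .test_cache$closure <- rule_closure("C34H42O19")
  }
  .test_cache$closure
}

cached_fixture <- function() {
  if (is.null(.test_cache$fixture)) {
    .test_cache$fixture <- load_table1_fixture()
  }
  .test_cache$fixture
}

# Independent brute-force formula enumerator: a plain grid filter over
# the full bounded lattice, no shared code with enumerate_formulas
# beyond the mass constants.
brute_force_formulas <- function(target, bounds) {
  m <- ISOTOPE_MASSES
  g <- expand.grid(C = bounds$C[1]:bounds$C[2], H = bounds$H[1]:bounds$H[2],
                   N = bounds$N[1]:bounds$N[2], O = bounds$O[1]:bounds$O[2],
                   S = bounds$S[1]:bounds$S[2], Na = bounds$Na[1]:bounds$Na[2],
                   KEEP.OUT.ATTRS = FALSE)
  mass <- g$C * m[["C"]] + g$H * m[["H"]] + g$N * m[["N"]] +
    g$O * m[["O"]] + g$S * m[["S"]] + g$Na * m[["Na"]]
  ppm <- 1e6 * (target - mass) / mass
  rdb <- g$C + 1 - (g$H + g$Na) / 2 + g$N / 2
  keep <- is.finite(ppm) & abs(ppm) <= bounds$tol_ppm &
    rdb >= bounds$rdb[1] & rdb <= bounds$rdb[2] & mass > 0
  g <- g[keep, , drop = FALSE]
  if (!nrow(g)) return(character())
  txt <- vapply(seq_len(nrow(g)), function(i) {
    format_formula(chem_formula(C = g$C[i], H = g$H[i], N = g$N[i],
                                O = g$O[i], S = g$S[i], Na = g$Na[i]))
  }, character(1))
  txt[order(abs(ppm[keep]), txt)]
}

# Independent two-sided p-value for a t statistic: numerical integration
# of the explicit t density, no use of pt().
numeric_t_p2 <- function(t, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  tail <- stats::integrate(dens, abs(t), Inf, rel.tol = 1e-10)$value
  2 * tail
}

# Random CHNOS formula within modest bounds, for property tests.
random_formula <- function() {
  chem_formula(C = sample(0:20, 1), H = sample(0:40, 1),
               N = sample(0:3, 1), O = sample(0:10, 1),
               S = sample(0:2, 1))
}
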