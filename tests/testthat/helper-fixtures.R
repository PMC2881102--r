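# Small study configurations used across tests; kept tiny so the module
# tests stay fast. Full-scale runs live in test-acceptance.R.

tiny_config <- function(n_features = 400, effects = list(), seed = 11,
                        flag_rate = 0.02, self_self_ratio_sd = 0.25) {
  study_config(n_features = n_features,
               planted_effects = effects,
               flag_rate = flag_rate,
               self_self_ratio_sd = self_self_ratio_sd,
               seed = seed)
}

# An array with prescribed intensities, defaulting to clean flags.
make_array <- function(f635, f532, flag = rep(0L, length(f635)),
                       ids = sprintf("G%03d", seq_along(f635)), ...) {
  two_color_array(ids, f635, f532, flag, ...)
}

# Independent Mann-Whitney U via direct pair counting (not ranks).
count_u <- function(x, y) {
  sum(vapply(x, function(xi) sum(xi > y) + 0.5 * sum(xi == y), numeric(1)))
}
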