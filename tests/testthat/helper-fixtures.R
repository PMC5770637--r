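# Shared fixture builders: all synthetic, generated in code at test time.

# Measurement records encoding an exactly known tracer allocation:
# `fracs` is a named vector (compartment -> fraction of the applied dose per
# plot); every plot carries the same truth unless `plot_jitter` scales it.
make_known_measurements <- function(fracs, pools, year = 2007, n_plots = 3,
                                    tracer = tracer_application(),
                                    natural_delta = -5) {
  rows <- list()
  ap_ref <- delta_to_atom_percent(natural_delta)
  for (p in seq_len(n_plots)) {
    for (cmp in names(fracs)) {
      m_pool <- pools$m_pool_gN_m2[pools$compartment == cmp &
                                     pools$year == year]
      mass <- fracs[[cmp]] * tracer$applied_excess_g_m2
      ap_lab <- ap_ref + mass / m_pool * (tracer$label_atom_percent - ap_ref)
      rows[[length(rows) + 1]] <- tibble::tibble(
        plot = p,
        role = c("labelled", "reference"),
        year = year, compartment = cmp,
        delta15n = c(atom_percent_to_delta(ap_lab), natural_delta),
        n_content = 0.01)
    }
  }
  dplyr::bind_rows(rows)
}

simple_pools <- function(years = 2007) {
  pool_series(
    data.frame(
      compartment = c("moss", "O_horizon", "A_horizon", "B_horizon",
                      "current_year_shoots", "shoots_1_2yr",
                      "litter_current"),
      m_pool_gN_m2 = c(8.5, 70, 170, 160, 1.2, 0.75, 0.3)),
    years = years)
}
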