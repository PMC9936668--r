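# shared fixtures: a shortened trial protocol and a small response surface
# so simulation-backed tests stay fast; quantification windows scale with
# the protocol

short_protocol <- function() trial_protocol(6, 12, 6, 4)

quiet_surface <- function(...) response_surface(rsa_depth = 0, ...)

# tiny deterministic factor table with additive effects of known size
balanced_table <- function(a_levels = c(0.8, 1), m_levels = c(10, 20),
                           a_effect = c(0, 1), m_effect = c(0, 1)) {
  g <- expand.grid(amplitude = a_levels, mpr = m_levels)
  g$frequency <- g$mpr
  g$animal <- "A1"
  g$y <- a_effect[match(g$amplitude, a_levels)] +
    m_effect[match(g$mpr, m_levels)]
  g
}
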