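# shared fixtures built in code

# prefers the flexible strategy at equal money but never beats money:
# indifference above the 1.97 display ceiling -> always picks the fixed 2 EUR
always_fixed_agent <- function(pair) {
  indifference_agent(pair[1], pair[2], mstar = 1.99)
}

# indifference below the display floor -> always keeps the flexible strategy
always_flexible_agent <- function(pair) {
  indifference_agent(pair[1], pair[2], mstar = 0.01)
}

# extract the displayed flexible-value sequence of a pairing result
flexible_display_sequence <- function(pairing) {
  tit <- pairing$records[pairing$records$phase == "titration", ]
  ifelse(tit$left_value == 2, tit$right_value, tit$left_value)
}

transitive_agent <- function(u_distraction = 0.9, u_distancing = 0.5,
                             u_suppression = 0.1) {
  agent(utilities = c(distraction = u_distraction,
                      distancing = u_distancing,
                      suppression = u_suppression))
}
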