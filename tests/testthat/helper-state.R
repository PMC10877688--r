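# Small constructors for hand-built community states.

new_state_with_one <- function(roster, lat, B, col, row, species = 1L) {
  gutsim:::new_community_state(lat, species = species, B = B,
                               col = as.integer(col), row = as.integer(row))
}

new_community_state_public <- function(lat) {
  gutsim:::new_community_state(lat)
}
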