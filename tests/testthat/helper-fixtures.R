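# 5 subjects x 3 conditions repeated-measures fixture; the frozen oracle
# values asserted in the tests were computed by hand from the textbook
# sum-of-squares and Greenhouse-Geisser formulas
rm_fixture <- function() {
  y <- c(12, 15, 19,
          8, 11, 14,
         10, 14, 13,
         14, 18, 22,
          9, 10, 15)
  data.frame(
    participant_id = rep(paste0("s", 1:5), each = 3),
    condition = rep(c("c1", "c2", "c3"), times = 5),
    value = y
  )
}
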