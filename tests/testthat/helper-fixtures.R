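# shared in-code fixtures

# a small, well-behaved stand table used where the real tables are overkill
toy_stand <- function() {
  stand_table(age = c(10, 20, 30), n = c(2000, 1500, 1000),
              d = c(8, 14, 18), h = c(5, 9, 11), f = c(0.8, 0.7, 0.6),
              label = "toy")
}

expect_rel_equal <- function(object, expected, rel_tol) {
  expect_lt(abs(object - expected) / abs(expected), rel_tol)
}
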