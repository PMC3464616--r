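# Published syndrome/pattern tables, frozen once and shared by the
# module and acceptance suites.

# Published single-error syndrome tables, frozen cell-for-cell.  Rows are
# error types +1, +a, +b; columns the positions p-, c1..c5, p+.
REF_SYNDROMES <- list(
  "1b0b0" = list(
    "+1" = c("10", "01", "ba", "ba", "01", "11", "01"),
    "+a" = c("a0", "0a", "1b", "1b", "0a", "aa", "0a"),
    "+b" = c("b0", "0b", "a1", "a1", "0b", "bb", "0b")),
  "10b00" = list(
    "+1" = c("10", "ab", "ab", "01", "01", "bb", "01"),
    "+a" = c("a0", "b1", "b1", "0a", "0a", "11", "0a"),
    "+b" = c("b0", "1a", "1a", "0b", "0b", "aa", "0b")),
  "1b010" = list(
    "+1" = c("10", "ba", "ab", "ab", "01", "aa", "01"),
    "+a" = c("a0", "1b", "b1", "b1", "0a", "bb", "0a"),
    "+b" = c("b0", "a1", "1a", "1a", "0b", "11", "0b")))

REF_CLASSES <- list(
  "1b0b0" = list(c("c1", "c4", "p+"), c("c2", "c3"), c("c5")),
  "10b00" = list(c("c1", "c2"), c("c3", "c4", "p+"), c("c5")),
  "1b010" = list(c("c1"), c("c2", "c3"), c("c4", "p+"), c("c5")))

# Published base-space miscorrection patterns (per unit error type +1).
REF_PATTERNS <- list(
  "1b0b0" = list(list("c2", "c3", "00100", "single"),
                 list("c4", "p+", "00001", "single"),
                 list("c1", "c4", "01110", "triple"),
                 list("c1", "p+", "01111", "quadruple")),
  "10b00" = list(list("c1", "c2", "01000", "single"),
                 list("c3", "c4", "00010", "single"),
                 list("c3", "p+", "00011", "double"),
                 list("c4", "p+", "00001", "single")),
  "1b010" = list(list("c2", "c3", "00100", "single"),
                 list("c4", "p+", "00001", "single")))

positions7 <- c("p-", "c1", "c2", "c3", "c4", "c5", "p+")
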