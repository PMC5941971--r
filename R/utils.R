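# Round half away from zero (round(12.5) -> 13, round(-12.5) -> -13).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Substitute the base at 1-based position i with a different base.
substitute_base <- function(s, i) {
  old <- substr(s, i, i)
  new <- sample(setdiff(DNA_BASES, old), 1L)
  substr(s, i, i) <- new
  s
}

reverse_string <- function(s) {
  paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
}

quality_rank <- function(q) {
  unname(c(high = 3L, medium = 2L, low = 1L)[q])
}
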