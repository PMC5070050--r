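# naive-loop morphology oracle shared by the unit and acceptance suites:
# closing fills interior still gaps shorter than m frames, opening erases
# movement runs shorter than m frames

oracle_close <- function(x, m) {
  y <- x; n <- length(x); i <- 1L
  while (i <= n) {
    if (!x[i]) {
      j <- i
      while (j < n && !x[j + 1L]) j <- j + 1L
      if (i > 1L && j < n && (j - i + 1L) < m) y[i:j] <- TRUE
      i <- j + 1L
    } else i <- i + 1L
  }
  y
}

oracle_open <- function(x, m) {
  y <- x; n <- length(x); i <- 1L
  while (i <= n) {
    if (x[i]) {
      j <- i
      while (j < n && x[j + 1L]) j <- j + 1L
      if ((j - i + 1L) < m) y[i:j] <- FALSE
      i <- j + 1L
    } else i <- i + 1L
  }
  y
}
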