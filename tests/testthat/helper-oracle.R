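# A deliberately naive per-offset scorer, coded independently of the
# package's scanning path, used as the oracle for scan/count equivalence.
naive_scan <- function(seq, pwm, threshold, bg = rep(0.25, 4)) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  w <- ncol(pwm$mat)
  out <- data.frame(start = integer(), strand = character(), llr = numeric())
  if (length(chars) < w) return(out)
  score1 <- function(sub) {
    if (any(!sub %in% bases)) return(NA_real_)
    s <- 0
    for (i in seq_len(w)) {
      s <- s + log(pwm$mat[sub[i], i] / bg[match(sub[i], bases)])
    }
    s
  }
  rc1 <- function(sub) rev(unname(c(A = "T", C = "G", G = "C", T = "A")[sub]))
  for (o in 0:(length(chars) - w)) {
    sub <- chars[(o + 1):(o + w)]
    sp <- score1(sub)
    sm <- if (any(!sub %in% bases)) NA_real_ else score1(rc1(sub))
    if (!is.na(sp) && sp > threshold) {
      out <- rbind(out, data.frame(start = o, strand = "+", llr = sp))
    }
    if (!is.na(sm) && sm > threshold) {
      out <- rbind(out, data.frame(start = o, strand = "-", llr = sm))
    }
  }
  out
}

random_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

# Toy transition-table cell used throughout: Pr[b | a = 2, lambda = 10].
toy_table <- function() {
  transition_table(tibble::tibble(
    a = 2, lambda_min = 10, lambda_max = 10,
    prob = list(c(0.5, 0.3, 0.15, 0.05))))
}

# A small random PWM with continuous score spread (tie-free with prob 1).
random_pwm <- function(width = 8L, seed = 1L, id = "rand") {
  m <- withr::with_seed(seed, matrix(stats::rgamma(4L * width, 1), nrow = 4L))
  pwm(m, id = id, pseudocount = 0.05)
}
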