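# Fixtures are built in code; nothing is read from disk except files the
# helpers themselves write into tempdir().

random_profile <- function(L, seed = NULL, id = "P1") {
  if (!is.null(seed)) set.seed(seed)
  pssm_profile(id,
               matrix(sample(-8:8, L * 20L, replace = TRUE), L, 20L),
               paste(sample(AA_ORDER, L, replace = TRUE), collapse = ""))
}

# Two well-separated Gaussian classes in `d` dimensions.
separable_data <- function(n_per_class, d = 10L, shift = 4, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
             matrix(rnorm(n_per_class * d, mean = shift), ncol = d))
  list(x = x, y = rep(c(0L, 1L), each = n_per_class))
}

# PSI-BLAST ASCII fixture: header, residue rows with both the 20-column
# log-odds block and 20 trailing weighted-percentage columns plus two
# floats, then statistics lines — the layout real PSI-BLAST emits.
write_psiblast_fixture <- function(path, scores, letters,
                                   extra_columns = TRUE) {
  header <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("            ", paste(sprintf("%3s", AA_ORDER), collapse = " "), "   ",
           paste(sprintf("%3s", AA_ORDER), collapse = " "))
  )
  rows <- vapply(seq_len(nrow(scores)), function(i) {
    line <- paste0(sprintf("%5d %s  ", i, letters[i]),
                   paste(sprintf("%3d", scores[i, ]), collapse = " "))
    if (extra_columns) {
      pct <- round(100 * abs(scores[i, ]) / max(1, sum(abs(scores[i, ]))))
      line <- paste0(line, "   ", paste(sprintf("%3d", pct), collapse = " "),
                     "  0.36 0.07")
    }
    line
  }, character(1))
  trailer <- c("", "                      K         Lambda",
               "Standard Ungapped    0.1347     0.3176",
               "PSI Ungapped         0.1347     0.3176")
  writeLines(c(header, rows, trailer), path)
  path
}
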