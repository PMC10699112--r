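# Independent oracles used across the suite.  These deliberately share
# no code with the package internals: the genetic code is taken from
# Biostrings, sites/differences are computed by direct enumeration, and
# p-values come from base R reference implementations.

oracle_code <- as.list(Biostrings::GENETIC_CODE)

oracle_translate <- function(codon) oracle_code[[codon]]

oracle_is_stop <- function(codon) identical(oracle_translate(codon), "*")

oracle_mutations <- function(codon) {
  # all 9 single-base variants of a codon
  out <- character(0)
  for (p in 1:3) for (b in c("A", "C", "G", "T")) {
    if (substr(codon, p, p) != b) {
      v <- codon
      substr(v, p, p) <- b
      out <- c(out, v)
    }
  }
  out
}

# NG86 site fractions by direct enumeration: per position, synonymous
# fraction among the changes that do not create a stop codon.
oracle_sites <- function(codon) {
  s <- 0
  for (p in 1:3) {
    syn <- 0; valid <- 0
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      v <- codon
      substr(v, p, p) <- b
      if (!oracle_is_stop(v)) {
        valid <- valid + 1
        if (oracle_translate(v) == oracle_translate(codon)) syn <- syn + 1
      }
    }
    if (valid > 0) s <- s + syn / valid
  }
  c(s = s, n = 3 - s)
}

# Pathway-enumeration oracle for the differences between two codons:
# recursively walks every ordering of the differing positions,
# classifies each step, drops pathways through stop codons (averaging
# over all pathways if every one is blocked).
oracle_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  paths <- list()
  walk <- function(cur, remaining, sd, nd, blocked) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1]] <<- list(sd = sd, nd = nd, blocked = blocked)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      step_syn <- !oracle_is_stop(cur) && !oracle_is_stop(nxt) &&
        oracle_translate(cur) == oracle_translate(nxt)
      walk(nxt, setdiff(remaining, p),
           sd + as.numeric(step_syn), nd + as.numeric(!step_syn),
           blocked || oracle_is_stop(nxt))
    }
  }
  walk(c1, pos, 0, 0, FALSE)
  ok <- !vapply(paths, `[[`, TRUE, "blocked")
  use <- if (any(ok)) paths[ok] else paths
  c(sd = mean(vapply(use, `[[`, 0, "sd")), nd = mean(vapply(use, `[[`, 0, "nd")))
}

# Random sense-codon sequence as a string.
random_sense_sequence <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

# Direct computation of the first GESD step (R_1 and lambda_1).
oracle_gesd_step1 <- function(x, alpha) {
  R1 <- max(abs(x - mean(x))) / sd(x)
  n <- length(x)
  t <- qt(1 - alpha / (2 * n), df = n - 2)
  lambda1 <- (n - 1) * t / sqrt((n - 2 + t^2) * n)
  c(R1 = R1, lambda1 = lambda1)
}
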