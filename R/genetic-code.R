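# Genetic-code utilities and NG86 site/difference tables.
#
# All downstream dN/dS computation works on integer codon indices in
# 1..64 (base-4 encoding of the trinucleotide, A=0, C=1, G=2, T=3) so
# that per-alignment work reduces to table lookups.

.ng86_env <- new.env(parent = emptyenv())

.BASES <- c("A", "C", "G", "T")

#' @keywords internal
codon_index <- function(codon) {
  stopifnot(all(nchar(codon) == 3L))
  m <- matrix(match(unlist(strsplit(toupper(codon), "")), .BASES) - 1L,
              ncol = 3L, byrow = TRUE)
  if (anyNA(m)) return(rep(NA_integer_, length(codon)) + ifelse(rowSums(is.na(m)) > 0, NA, 0L))
  as.integer(m %*% c(16L, 4L, 1L) + 1L)
}

#' @keywords internal
index_codon <- function(idx) {
  idx <- idx - 1L
  paste0(.BASES[idx %/% 16L + 1L], .BASES[(idx %/% 4L) %% 4L + 1L], .BASES[idx %% 4L + 1L])
}

# Amino acid (one-letter, "*" = stop) for codon indices 1..64, standard code.
genetic_code_vector <- function() {
  if (is.null(.ng86_env$aa)) {
    gc <- Biostrings::GENETIC_CODE
    idx <- codon_index(names(gc))
    aa <- character(64L)
    aa[idx] <- unname(gc)
    .ng86_env$aa <- aa
  }
  .ng86_env$aa
}

# For codon index i and position p (1..3), the 3 codon indices reachable
# by a single-base change at p.  Returned as a 64 x 3 x 3 integer array.
codon_neighbors <- function() {
  if (is.null(.ng86_env$nbr)) {
    nbr <- array(NA_integer_, dim = c(64L, 3L, 3L))
    mult <- c(16L, 4L, 1L)
    for (i in 1:64) {
      d <- i - 1L
      dig <- c(d %/% 16L, (d %/% 4L) %% 4L, d %% 4L)
      for (p in 1:3) {
        alt <- setdiff(0:3, dig[p])
        nbr[i, p, ] <- as.integer(d + (alt - dig[p]) * mult[p] + 1L)
      }
    }
    .ng86_env$nbr <- nbr
  }
  .ng86_env$nbr
}

#' Synonymous and nonsynonymous site fractions of a codon
#'
#' Counts, per Nei and Gojobori (1986), the fraction of single-base
#' changes at each codon position that are synonymous.  Changes that
#' would create a stop codon are excluded from the denominator, so each
#' position contributes exactly one site and `s + n == 3` for every
#' sense codon.
#'
#' @param codon A single sense codon, e.g. `"GGG"`.
#' @return Named numeric vector with elements `s` (synonymous sites) and
#'   `n` (nonsynonymous sites), summing to 3.
#' @examples
#' ng86_codon_sites("GGG")  # s = 1: third position fully synonymous
#' ng86_codon_sites("ATG")  # s = 0: Met has no synonymous neighbour
#' @export
ng86_codon_sites <- function(codon) {
  if (length(codon) != 1L || !is.character(codon) || nchar(codon) != 3L)
    stop("`codon` must be a single 3-letter string")
  codon <- toupper(codon)
  if (!all(strsplit(codon, "")[[1]] %in% .BASES))
    stop("ambiguous or non-ACGT codon: ", codon)
  idx <- codon_index(codon)
  aa <- genetic_code_vector()
  if (aa[idx] == "*") stop("stop codon has no defined site counts: ", codon)
  s <- ng86_site_table()[idx]
  c(s = s, n = 3 - s)
}

# Synonymous-site count for every codon index (NA for stops).
ng86_site_table <- function() {
  if (is.null(.ng86_env$sites)) {
    aa <- genetic_code_vector()
    nbr <- codon_neighbors()
    s <- rep(NA_real_, 64L)
    for (i in which(aa != "*")) {
      tot <- 0
      for (p in 1:3) {
        alt <- nbr[i, p, ]
        keep <- aa[alt] != "*"
        if (any(keep)) tot <- tot + sum(aa[alt[keep]] == aa[i]) / sum(keep)
        # a position with only stop-creating changes would contribute 0
      }
      s[i] <- tot
    }
    .ng86_env$sites <- s
  }
  .ng86_env$sites
}

# Pathway-averaged synonymous/nonsynonymous difference counts for every
# ordered pair of sense codons.  Differences between two codons are
# attributed by enumerating all orderings of the differing positions
# (1, 2 or 6 pathways), discarding pathways whose intermediate codons
# are stops, and averaging the per-step classifications over the
# admissible pathways.  If every pathway is blocked by a stop the
# average is taken over all pathways instead and the pair is flagged.
ng86_diff_tables <- function() {
  if (is.null(.ng86_env$sd_mat)) {
    aa <- genetic_code_vector()
    sd_mat <- matrix(NA_real_, 64L, 64L)
    nd_mat <- matrix(NA_real_, 64L, 64L)
    blocked <- matrix(FALSE, 64L, 64L)
    sense <- which(aa != "*")
    mult <- c(16L, 4L, 1L)
    digits <- function(i) { d <- i - 1L; c(d %/% 16L, (d %/% 4L) %% 4L, d %% 4L) }
    perms2 <- list(c(1L, 2L), c(2L, 1L))
    perms3 <- list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L), c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L))
    for (i in sense) {
      di <- digits(i)
      for (j in sense) {
        if (j < i) next
        dj <- digits(j)
        pos <- which(di != dj)
        nd <- length(pos)
        if (nd == 0L) { sd_mat[i, j] <- 0; nd_mat[i, j] <- 0; next }
        perms <- switch(nd, list(pos), lapply(perms2, function(o) pos[o]),
                        lapply(perms3, function(o) pos[o]))
        path_sd <- path_nd <- numeric(0)
        ok <- logical(0)
        for (ord in perms) {
          cur <- di; sdp <- 0; ndp <- 0; admissible <- TRUE
          prev_idx <- i
          for (p in ord) {
            cur[p] <- dj[p]
            nxt <- as.integer(sum(cur * mult) + 1L)
            if (aa[nxt] == "*") { admissible <- FALSE }
            if (aa[nxt] == aa[prev_idx] && aa[nxt] != "*" && aa[prev_idx] != "*") {
              sdp <- sdp + 1
            } else {
              ndp <- ndp + 1
            }
            prev_idx <- nxt
          }
          path_sd <- c(path_sd, sdp); path_nd <- c(path_nd, ndp); ok <- c(ok, admissible)
        }
        if (any(ok)) {
          sd_mat[i, j] <- mean(path_sd[ok]); nd_mat[i, j] <- mean(path_nd[ok])
        } else {
          sd_mat[i, j] <- mean(path_sd); nd_mat[i, j] <- mean(path_nd)
          blocked[i, j] <- blocked[j, i] <- TRUE
        }
        sd_mat[j, i] <- sd_mat[i, j]; nd_mat[j, i] <- nd_mat[i, j]
      }
    }
    .ng86_env$sd_mat <- sd_mat
    .ng86_env$nd_mat <- nd_mat
    .ng86_env$blocked <- blocked
  }
  list(sd = .ng86_env$sd_mat, nd = .ng86_env$nd_mat, blocked = .ng86_env$blocked)
}

#' Sense codons of the standard genetic code
#' @return Character vector of the 61 sense codons.
#' @export
sense_codons <- function() {
  aa <- genetic_code_vector()
  index_codon(which(aa != "*"))
}
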