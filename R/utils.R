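#' @keywords internal
"_PACKAGE"

# Internal coordinates are 0-based half-open; everything written to or read
# from disk is 1-based inclusive. Conversion happens only at the IO boundary.

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

revcomp_chr <- function(x) {
  vapply(strsplit(x, ""), function(b) paste(rev(unname(COMP[b])), collapse = ""), "")
}

#' The 96 single-base-substitution channels
#'
#' Pyrimidine-centred trinucleotide contexts crossed with the six
#' substitution types, in the conventional COSMIC ordering
#' (e.g. \code{"A[C>T]G"}).
#'
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    for (up in BASES) {
      for (dn in BASES) {
        out <- c(out, paste0(up, "[", s, "]", dn))
      }
    }
  }
  out
}

# Collapse a strand-specific substitution with flanks to its pyrimidine
# channel. Vectorised over all arguments.
sbs_channel <- function(up, ref, alt, dn) {
  flip <- ref %in% c("A", "G")
  u <- ifelse(flip, unname(COMP[dn]), up)
  d <- ifelse(flip, unname(COMP[up]), dn)
  r <- ifelse(flip, unname(COMP[ref]), ref)
  a <- ifelse(flip, unname(COMP[alt]), alt)
  paste0(u, "[", r, ">", a, "]", d)
}

# Beta-binomial with mean mu and intra-class correlation rho.
# rho below the floor degrades gracefully to the binomial.
dbetabinom <- function(x, size, mu, rho, log = FALSE) {
  if (rho < 1e-12) {
    return(stats::dbinom(x, size, mu, log = log))
  }
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  lp <- lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
  if (log) lp else exp(lp)
}

# Upper tail P(X >= q). Exact summation; depths here are at most a few
# thousand so the direct sum is cheap and avoids approximation error.
pbetabinom_upper <- function(q, size, mu, rho) {
  if (q <= 0) return(1)
  if (q > size) return(0)
  if (rho < 1e-12) {
    return(stats::pbinom(q - 1, size, mu, lower.tail = FALSE))
  }
  sum(dbetabinom(q:size, size, mu, rho))
}

rbetabinom <- function(n, size, mu, rho) {
  if (rho < 1e-12) return(stats::rbinom(n, size, mu))
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  p <- stats::rbeta(n, a, b)
  stats::rbinom(n, size, p)
}

# Deterministic per-stage seed derived from a master seed, kept inside the
# 32-bit integer range so the stream is reproducible across platforms.
stage_seed <- function(seed, stage) {
  offsets <- c(genes = 11L, epidermis = 23L, tumor = 37L, panel = 53L,
               call = 67L, filter = 79L, select = 97L, colonize = 113L,
               cna = 131L, clonality = 149L, report = 163L, misc = 179L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
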