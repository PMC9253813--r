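# Shared small helpers. Internal coordinates are 0-based half-open [start,
# end) on the forward genomic strand throughout; strand is metadata.
# Conversion to/from 1-based closed happens only at I/O boundaries.

#' Round half-up
#'
#' Rounds to `digits` decimals with ties going away from zero, matching how
#' report percentages are conventionally printed (base `round()` rounds half
#' to even).
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
#' @examples
#' round_half_up(0.125, 2)  # 0.13, where round() gives 0.12
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Format a count ratio as a printed percentage
#'
#' `fmt_pct(n, d)` renders `100 * n / d` rounded half-up to two decimals with
#' a trailing percent sign, the convention used in all summary tables. A zero
#' denominator prints `"NA"`.
#'
#' @param n numerator count(s)
#' @param d denominator count(s)
#' @param digits decimal places (default 2)
#' @return character vector like `"91.17%"`
#' @export
#' @examples
#' fmt_pct(207967, 228106)
fmt_pct <- function(n, d, digits = 2) {
  out <- ifelse(d == 0, NA_real_, round_half_up(100 * n / d, digits))
  ifelse(is.na(out), "NA", paste0(sprintf(paste0("%.", digits, "f"), out), "%"))
}

# 1-based closed -> 0-based half-open
gff_to_internal <- function(start1, end1) cbind(start = start1 - 1L, end = end1)

# 0-based half-open -> 1-based closed
internal_to_gff <- function(start0, end0) cbind(start = start0 + 1L, end = end0)

# overlap length of [s1,e1) and [s2,e2); vectorized
overlap_len <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))

# canonical string key for a junction chain (genomic order)
chain_key <- function(chrom, strand, junctions) {
  if (is.null(junctions) || nrow(junctions) == 0) {
    return(paste(chrom, strand, ".", sep = "|"))
  }
  paste(chrom, strand,
        paste(junctions[, 1], junctions[, 2], sep = "-", collapse = ","),
        sep = "|")
}

# junction matrix (gap_start, gap_end) from an exon block matrix [start,end)
blocks_to_junctions <- function(blocks) {
  nb <- nrow(blocks)
  if (nb < 2) return(matrix(integer(0), ncol = 2,
                            dimnames = list(NULL, c("start", "end"))))
  cbind(start = blocks[seq_len(nb - 1), 2], end = blocks[seq(2, nb), 1])
}

# exon block matrix from junctions plus the span endpoints
junctions_to_blocks <- function(span_start, span_end, junctions) {
  if (is.null(junctions) || nrow(junctions) == 0) {
    return(cbind(start = span_start, end = span_end))
  }
  cbind(start = c(span_start, junctions[, 2]),
        end = c(junctions[, 1], span_end))
}

# union-find over 1..n returning component labels; used where igraph would be
# heavier than needed
components_from_edges <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(from)) {
    a <- find(from[k]); b <- find(to[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), find, integer(1))
}

# deterministic zero-padded ids
make_ids <- function(prefix, n) sprintf("%s%06d", prefix, seq_len(n))

pairs_overlapping <- function(start, end) {
  # all index pairs (i < j) whose [start, end) intervals overlap; sweep after
  # sorting by start so runtime tracks the number of overlaps
  n <- length(start)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  ord <- order(start, end)
  res_i <- integer(0); res_j <- integer(0)
  active <- integer(0)
  for (k in ord) {
    if (length(active)) {
      keep <- end[active] > start[k]
      active <- active[keep]
      if (length(active)) {
        res_i <- c(res_i, pmin(active, k))
        res_j <- c(res_j, pmax(active, k))
      }
    }
    active <- c(active, k)
  }
  cbind(res_i, res_j)
}
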