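# Alternative-splicing event enumeration: exon skipping (ES), alternative
# acceptor (AA), alternative donor (AD), intron retention (IR), other.

#' Classify the AS events between two isoforms of one locus
#'
#' Structural differences between the two junction chains are assigned, in
#' order of precedence:
#' * **ES** - an internal exon of one isoform is absent from the other, which
#'   instead carries a junction spanning the exon with both flanking splice
#'   sites shared; one event per skipped exon.
#' * **IR** - one isoform's exon fully contains the other's intron together
#'   with both of its splice sites.
#' * **AA / AD** - two junctions share their donor but differ at the acceptor
#'   (AA), or share the acceptor and differ at the donor (AD). Donor and
#'   acceptor follow transcript orientation, so the AA/AD labels swap when
#'   the strand flips.
#' * **other** - any remaining junction difference (alternative first/last
#'   exons, mutually exclusive exons, complex patterns).
#'
#' Identical chains (possible only for differing TSS/TES, which collapse
#' leaves merged) produce no events. The result is orientation-normalized:
#' `classify_as_pair(A, B)` equals `classify_as_pair(B, A)`.
#'
#' @param iso_a,iso_b single-row isoform tibbles (or lists) with `chrom`,
#'   `strand`, `start`, `end`, `junctions`.
#' @return tibble of events: `type`, `start`, `end`, `signature`.
#' @export
classify_as_pair <- function(iso_a, iso_b) {
  chrom <- iso_a$chrom[[1]]; strand <- iso_a$strand[[1]]
  ja <- iso_a$junctions[[1]]; jb <- iso_b$junctions[[1]]
  span_a <- c(iso_a$start[[1]], iso_a$end[[1]])
  span_b <- c(iso_b$start[[1]], iso_b$end[[1]])
  key <- function(j) if (nrow(j) == 0) character(0) else paste0(j[, 1], "-", j[, 2])
  ka <- key(ja); kb <- key(jb)
  ua <- which(!(ka %in% kb))  # junction rows unique to A
  ub <- which(!(kb %in% ka))
  used_a <- logical(nrow(ja)); used_b <- logical(nrow(jb))
  ev <- list()
  emit <- function(type, s, e) {
    s <- unname(s); e <- unname(e)
    ev[[length(ev) + 1]] <<- tibble(type = type, start = s, end = e,
                                    signature = paste(type, chrom, strand,
                                                      s, e, sep = ":"))
  }

  # --- exon skipping: spanning junction in one, flanked exon(s) in the other
  find_es <- function(jspan, uspan_used, jexons, span_ex) {
    # jspan: (s,e) junction of the "exclusion" isoform; jexons: junctions of
    # the "inclusion" isoform. Returns skipped exon intervals or NULL.
    s <- jspan[1]; e <- jspan[2]
    left <- which(jexons[, 1] == s & jexons[, 2] < e)
    right <- which(jexons[, 2] == e & jexons[, 1] > s)
    if (length(left) == 0 || length(right) == 0) return(NULL)
    li <- left[1]; ri <- right[length(right)]
    if (ri < li) return(NULL)
    inner <- seq(li, ri)
    # exons between consecutive junctions li..ri
    ex_s <- jexons[inner[-length(inner)], 2]
    ex_e <- jexons[inner[-1], 1]
    if (length(inner) == 1) { ex_s <- jexons[li, 2]; ex_e <- jexons[ri, 1] }
    if (length(ex_s) == 0) return(NULL)
    list(exon_start = ex_s, exon_end = ex_e, consumed = inner)
  }
  for (bi in ub) {
    if (used_b[bi]) next
    hit <- find_es(jb[bi, ], NULL, ja, span_a)
    if (!is.null(hit) && length(hit$exon_start) > 0 &&
        all(hit$exon_start < hit$exon_end)) {
      used_b[bi] <- TRUE
      used_a[hit$consumed] <- TRUE
      for (k in seq_along(hit$exon_start)) {
        emit("ES", hit$exon_start[k], hit$exon_end[k])
      }
    }
  }
  for (ai in ua) {
    if (used_a[ai]) next
    hit <- find_es(ja[ai, ], NULL, jb, span_b)
    if (!is.null(hit) && length(hit$exon_start) > 0 &&
        all(hit$exon_start < hit$exon_end)) {
      used_a[ai] <- TRUE
      used_b[hit$consumed] <- TRUE
      for (k in seq_along(hit$exon_start)) {
        emit("ES", hit$exon_start[k], hit$exon_end[k])
      }
    }
  }

  # --- intron retention: intron of one inside an exon of the other
  exons_a <- junctions_to_blocks(span_a[1], span_a[2], ja)
  exons_b <- junctions_to_blocks(span_b[1], span_b[2], jb)
  retained_in <- function(j, exons) {
    any(exons[, 1] < j[1] & exons[, 2] > j[2])
  }
  for (bi in ub) {
    if (used_b[bi]) next
    if (retained_in(jb[bi, ], exons_a)) {
      used_b[bi] <- TRUE
      emit("IR", jb[bi, 1], jb[bi, 2])
    }
  }
  for (ai in ua) {
    if (used_a[ai]) next
    if (retained_in(ja[ai, ], exons_b)) {
      used_a[ai] <- TRUE
      emit("IR", ja[ai, 1], ja[ai, 2])
    }
  }

  # --- alternative acceptor / donor; candidate pairs collected then accepted
  # greedily in coordinate order so the result is symmetric in (A, B)
  cand <- list()
  for (ai in ua) {
    if (used_a[ai]) next
    for (bi in ub) {
      if (used_b[bi]) next
      share_start <- ja[ai, 1] == jb[bi, 1] && ja[ai, 2] != jb[bi, 2]
      share_end <- ja[ai, 2] == jb[bi, 2] && ja[ai, 1] != jb[bi, 1]
      if (!share_start && !share_end) next
      # gap start is the donor on '+', the acceptor on '-'
      type <- if (share_start) {
        if (strand == "+") "AA" else "AD"
      } else {
        if (strand == "+") "AD" else "AA"
      }
      cand[[length(cand) + 1]] <- list(
        ai = ai, bi = bi, type = type,
        s = min(ja[ai, ], jb[bi, ]), e = max(ja[ai, ], jb[bi, ]))
    }
  }
  if (length(cand) > 0) {
    ord <- order(vapply(cand, `[[`, numeric(1), "s"),
                 vapply(cand, `[[`, numeric(1), "e"),
                 vapply(cand, `[[`, character(1), "type"))
    for (p in cand[ord]) {
      if (used_a[p$ai] || used_b[p$bi]) next
      used_a[p$ai] <- TRUE; used_b[p$bi] <- TRUE
      emit(p$type, p$s, p$e)
    }
  }

  # --- everything else
  for (ai in ua) if (!used_a[ai]) emit("other", ja[ai, 1], ja[ai, 2])
  for (bi in ub) if (!used_b[bi]) emit("other", jb[bi, 1], jb[bi, 2])

  if (length(ev) == 0) {
    return(tibble(type = character(), start = numeric(), end = numeric(),
                  signature = character()))
  }
  bind_rows(ev) |> distinct(.data$signature, .keep_all = TRUE) |>
    arrange(.data$start, .data$end, .data$type)
}

#' Enumerate deduplicated AS events per locus
#'
#' Compares every isoform pair within each multi-isoform locus and counts
#' each distinct `(type, coordinates)` signature once per locus - the
#' counting convention for whole-dataset event totals. Single-isoform loci
#' contribute nothing.
#'
#' @param isoforms isoform tibble with `locus_id`.
#' @return list with `events` (tibble: `locus_id`, `type`, `start`, `end`,
#'   `signature`) and `counts` (tibble: `type`, `n` over the fixed levels ES,
#'   AA, AD, IR, other).
#' @export
enumerate_as_events <- function(isoforms) {
  ev <- list()
  for (lid in unique(isoforms$locus_id)) {
    ix <- which(isoforms$locus_id == lid)
    if (length(ix) < 2) next
    loc_ev <- list()
    for (a in seq_along(ix)[-length(ix)]) {
      for (b in seq(a + 1, length(ix))) {
        e <- classify_as_pair(isoforms[ix[a], ], isoforms[ix[b], ])
        if (nrow(e) > 0) loc_ev[[length(loc_ev) + 1]] <- e
      }
    }
    if (length(loc_ev) > 0) {
      ev[[lid]] <- bind_rows(loc_ev) |>
        distinct(.data$signature, .keep_all = TRUE) |>
        mutate(locus_id = lid, .before = 1)
    }
  }
  events <- if (length(ev)) bind_rows(ev) else
    tibble(locus_id = character(), type = character(), start = numeric(),
           end = numeric(), signature = character())
  lev <- c("ES", "AA", "AD", "IR", "other")
  counts <- tibble(type = lev,
                   n = vapply(lev, function(t) sum(events$type == t),
                              integer(1)))
  list(events = events, counts = counts)
}
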