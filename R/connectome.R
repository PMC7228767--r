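#' Controlled cell-type vocabulary
#'
#' Closed label set used by annotations and tallies. Subtype labels imply
#' their parent for tallying: the ON cone bipolar subtypes fold to `ON_CB`,
#' and the named amacrine subtypes (`NOS1_AC`, `DAC`) fold to `AC`.
#'
#' @return character vector of labels
#' @export
cell_types <- function() {
  c("AII", "RB", "ON_CB", "ON_CB5", "ON_CB6", "ON_CB7", "ON_CB8", "OFF_CB",
    "AC", "NOS1_AC", "A17", "DAC", "SAC_ON", "SAC_OFF", "GC", "UNIDENTIFIED")
}

#' @rdname cell_types
#' @param label character vector of type labels (any case, `-` for `_`)
#' @return `canonical_cell_type`: canonical label or `NA` when not in the
#'   vocabulary
#' @export
canonical_cell_type <- function(label) {
  lab <- toupper(gsub("-", "_", label))
  ok <- lab %in% cell_types()
  lab[!ok] <- NA_character_
  lab
}

#' @rdname cell_types
#' @return `parent_cell_type`: the tally-level parent of each label
#' @export
parent_cell_type <- function(label) {
  map <- c(ON_CB5 = "ON_CB", ON_CB6 = "ON_CB", ON_CB7 = "ON_CB",
           ON_CB8 = "ON_CB", NOS1_AC = "AC", DAC = "AC")
  ifelse(label %in% names(map), unname(map[label]), label)
}

bipolar_types <- function() c("RB", "ON_CB", "ON_CB5", "ON_CB6", "ON_CB7",
                              "ON_CB8", "OFF_CB")

empty_synapse_table <- function() {
  data.frame(synapse_id = integer(), pre_id = integer(), pre_type = character(),
             post_id = integer(), post_type = character(), kind = character(),
             x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
             depth = numeric(), compartment = character(),
             provenance = character(), pre_node = integer(),
             post_node = integer(), kind_flag = logical(),
             stringsAsFactors = FALSE)
}

# positions (nm) of every annotation row
annotation_positions <- function(forest) {
  a <- forest$annotations
  pos <- matrix(NA_real_, nrow(a), 3)
  for (sid in unique(a$skeleton_id)) {
    sk <- forest$skeletons[[as.character(sid)]]
    p <- node_phys(sk, forest$scale)
    rows <- which(a$skeleton_id == sid)
    pos[rows, ] <- p[as.character(a$node_id[rows]), , drop = FALSE]
  }
  colnames(pos) <- c("x_nm", "y_nm", "z_nm")
  pos
}

#' Build the typed synapse table
#'
#' Turns node-level annotations into directed synapse records. Pairing of the
#' pre-side (output) and post-side (input) marks proceeds in two passes:
#' first by declared partner id (an output on cell A naming partner B pairs
#' with an input on B naming A, of the same kind, closest first); remaining
#' marks are paired by proximity — same kind, different cells, physical
#' distance at most `epsilon_nm`, greedily by ascending distance, each mark
#' used at most once. Marks that stay unpaired become one-sided records
#' (provenance `pre-only` / `post-only`) whose partner is taken from the
#' annotation's partner type; they still count in tallies, matching
#' single-observer annotation practice (use `strict = TRUE` downstream to
#' restrict to two-sided records). Ribbon records whose presynaptic cell is
#' not a bipolar type are flagged (`kind_flag`), not dropped.
#'
#' @param forest a [skeleton_forest()]
#' @param frame optional [ipl_frame()]; fills the `depth` column
#' @param types named map skeleton_id -> cell type (defaults to
#'   [types_from_names()]); every annotated skeleton needs an entry
#'   (`UNIDENTIFIED` allowed)
#' @param pairing list(epsilon_nm = 500, use_ids = TRUE)
#' @param soma_radius_um geodesic soma radius for compartments (default 5)
#' @return data.frame of synapse records (one row per synapse)
#' @export
build_synapse_table <- function(forest, frame = NULL, types = NULL,
                                pairing = list(), soma_radius_um = 5) {
  eps <- pairing$epsilon_nm %||% 500
  use_ids <- pairing$use_ids %||% TRUE
  a <- forest$annotations
  if (!nrow(a)) return(empty_synapse_table())
  types <- types %||% types_from_names(forest)
  need <- as.character(unique(a$skeleton_id))
  miss <- setdiff(need, names(types))
  if (length(miss))
    stopf("no cell-type entry for annotated skeleton(s): %s",
          paste(miss, collapse = ", "))
  pos <- annotation_positions(forest)
  out_i <- which(a$direction == "output")
  in_i <- which(a$direction == "input")
  used_out <- logical(length(out_i)); used_in <- logical(length(in_i))
  pairs <- data.frame(o = integer(), i = integer(), prov = character())

  pair_up <- function(cand, prov) {
    # cand: data.frame(oi, ii, d) candidate pairs; greedy by ascending d
    cand <- cand[order(cand$d), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      oi <- cand$oi[r]; ii <- cand$ii[r]
      if (used_out[oi] || used_in[ii]) next
      used_out[oi] <<- TRUE; used_in[ii] <<- TRUE
      pairs <<- rbind(pairs, data.frame(o = oi, i = ii, prov = prov))
    }
  }

  if (use_ids && length(out_i) && length(in_i)) {
    cand <- NULL
    for (oi in seq_along(out_i)) {
      o <- out_i[oi]
      if (is.na(a$partner_cell_id[o])) next
      ii <- which(a$skeleton_id[in_i] == a$partner_cell_id[o] &
                    !is.na(a$partner_cell_id[in_i]) &
                    a$partner_cell_id[in_i] == a$skeleton_id[o] &
                    a$syn_kind[in_i] == a$syn_kind[o])
      # a declared mutual id pair whose kinds never agree is a conflict
      ii_any <- which(a$skeleton_id[in_i] == a$partner_cell_id[o] &
                        !is.na(a$partner_cell_id[in_i]) &
                        a$partner_cell_id[in_i] == a$skeleton_id[o])
      if (!length(ii) && length(ii_any))
        stopf("conflicting kinds for id-matched pair %d -> %d (nodes %s / %s)",
              a$skeleton_id[o], a$partner_cell_id[o], a$node_id[o],
              paste(a$node_id[in_i[ii_any]], collapse = ","))
      if (!length(ii)) next
      d <- sqrt(rowSums((pos[in_i[ii], , drop = FALSE] -
                           matrix(pos[o, ], length(ii), 3, byrow = TRUE))^2))
      cand <- rbind(cand, data.frame(oi = oi, ii = ii, d = d))
    }
    if (!is.null(cand) && nrow(cand)) pair_up(cand, "id-matched")
  }

  # proximity pass over whatever is left
  ro <- which(!used_out); ri <- which(!used_in)
  if (length(ro) && length(ri)) {
    cand <- NULL
    for (oi in ro) {
      o <- out_i[oi]
      ii <- ri[a$syn_kind[in_i[ri]] == a$syn_kind[o] &
                 a$skeleton_id[in_i[ri]] != a$skeleton_id[o]]
      if (!length(ii)) next
      d <- sqrt(rowSums((pos[in_i[ii], , drop = FALSE] -
                           matrix(pos[o, ], length(ii), 3, byrow = TRUE))^2))
      keep <- d <= eps
      if (any(keep))
        cand <- rbind(cand, data.frame(oi = oi, ii = ii[keep], d = d[keep]))
    }
    if (!is.null(cand) && nrow(cand)) pair_up(cand, "proximity")
  }

  rec <- list()
  add <- function(pre_id, post_id, kind, p, prov, pre_node, post_node) {
    pre_type <- if (is.na(pre_id)) NA_character_ else
      unname(types[as.character(pre_id)])
    post_type <- if (is.na(post_id)) NA_character_ else
      unname(types[as.character(post_id)])
    list(pre_id = pre_id, post_id = post_id, pre_type = pre_type,
         post_type = post_type, kind = kind,
         x_nm = p[1], y_nm = p[2], z_nm = p[3], prov = prov,
         pre_node = pre_node, post_node = post_node)
  }
  for (r in seq_len(nrow(pairs))) {
    o <- out_i[pairs$o[r]]; i <- in_i[pairs$i[r]]
    rec[[length(rec) + 1L]] <- add(a$skeleton_id[o], a$skeleton_id[i],
                                   a$syn_kind[o], (pos[o, ] + pos[i, ]) / 2,
                                   pairs$prov[r], a$node_id[o], a$node_id[i])
  }
  for (oi in which(!used_out)) {
    o <- out_i[oi]
    x <- add(a$skeleton_id[o], a$partner_cell_id[o], a$syn_kind[o], pos[o, ],
             "pre-only", a$node_id[o], NA_integer_)
    if (is.na(x$post_type)) x$post_type <- a$partner_type[o]
    rec[[length(rec) + 1L]] <- x
  }
  for (ii in which(!used_in)) {
    i <- in_i[ii]
    x <- add(a$partner_cell_id[i], a$skeleton_id[i], a$syn_kind[i], pos[i, ],
             "post-only", NA_integer_, a$node_id[i])
    if (is.na(x$pre_type)) x$pre_type <- a$partner_type[i]
    rec[[length(rec) + 1L]] <- x
  }
  if (!length(rec)) return(empty_synapse_table())
  tab <- data.frame(
    synapse_id = seq_along(rec),
    pre_id = vapply(rec, function(r) as.integer(r$pre_id), integer(1)),
    pre_type = vapply(rec, function(r) r$pre_type, character(1)),
    post_id = vapply(rec, function(r) as.integer(r$post_id), integer(1)),
    post_type = vapply(rec, function(r) r$post_type, character(1)),
    kind = vapply(rec, function(r) r$kind, character(1)),
    x_nm = vapply(rec, function(r) r$x_nm, numeric(1)),
    y_nm = vapply(rec, function(r) r$y_nm, numeric(1)),
    z_nm = vapply(rec, function(r) r$z_nm, numeric(1)),
    depth = NA_real_, compartment = "unassigned",
    provenance = vapply(rec, function(r) r$prov, character(1)),
    pre_node = vapply(rec, function(r) as.integer(r$pre_node), integer(1)),
    post_node = vapply(rec, function(r) as.integer(r$post_node), integer(1)),
    stringsAsFactors = FALSE)
  tab$kind_flag <- tab$kind == "ribbon" &
    !is.na(tab$pre_type) & !(tab$pre_type %in% bipolar_types())
  if (!is.null(frame))
    tab$depth <- ipl_depth(cbind(tab$x_nm, tab$y_nm, tab$z_nm), frame)
  tab$compartment <- assign_compartment(tab, forest, frame,
                                        soma_radius_um = soma_radius_um)
  tab
}

#' Derive cell types from skeleton names
#'
#' Convention: a skeleton name starting with a vocabulary label (for example
#' `AII_3`, `NOS1_AC_2`, `axon_AC_17`) maps to that label; anything else maps
#' to `UNIDENTIFIED`.
#'
#' @param forest a [skeleton_forest()]
#' @return named character vector, skeleton id -> type
#' @export
types_from_names <- function(forest) {
  labs <- vapply(forest$skeletons, function(s) s$name, character(1))
  out <- rep("UNIDENTIFIED", length(labs))
  vocab <- cell_types()[order(nchar(cell_types()), decreasing = TRUE)]
  for (v in vocab) {
    hit <- grepl(paste0("(^|_)", v, "(_|$)"), gsub("-", "_", toupper(labs)))
    out[hit & out == "UNIDENTIFIED"] <- v
  }
  names(out) <- names(forest$skeletons)
  out
}

#' Assign synaptic compartments on the postsynaptic cell
#'
#' `soma` when the geodesic distance from the synapse-bearing node to the
#' declared soma node is at most `soma_radius_um`; otherwise
#' `distal_dendrite` when the record's depth reaches the ON-side threshold
#' (at or vitreal to the ON SAC plane, minus `distal_slack`); otherwise
#' `proximal_dendrite`; `unassigned` when neither a soma node nor a depth is
#' available.
#'
#' @param tab synapse table rows (needs `post_id`, `post_node`, `depth`)
#' @param forest a [skeleton_forest()]
#' @param frame optional [ipl_frame()] (depths must already be in `tab`)
#' @param soma_radius_um default 5
#' @param distal_slack depth slack below the ON plane (default 0.1)
#' @return character vector of compartments
#' @export
assign_compartment <- function(tab, forest, frame = NULL, soma_radius_um = 5,
                               distal_slack = 0.1) {
  n <- nrow(tab)
  comp <- rep("unassigned", n)
  soma_maps <- list()  # per-skeleton geodesic distance-to-soma, computed once
  for (r in seq_len(n)) {
    sid <- as.character(tab$post_id[r])
    sk <- if (!is.na(tab$post_id[r])) forest$skeletons[[sid]] else NULL
    if (!is.null(sk) && !is.null(sk$soma_node) && !is.na(tab$post_node[r])) {
      if (is.null(soma_maps[[sid]]))
        soma_maps[[sid]] <- geodesic_from(sk, sk$soma_node, forest$scale)
      d <- soma_maps[[sid]][as.character(tab$post_node[r])]
      if (!is.na(d) && d <= soma_radius_um) { comp[r] <- "soma"; next }
    }
    if (!is.na(tab$depth[r]))
      comp[r] <- if (tab$depth[r] >= 1 - distal_slack) "distal_dendrite"
                 else "proximal_dendrite"
  }
  comp
}

new_tally <- function(df, focal, direction, total) {
  structure(df, class = c("tally_table", "data.frame"),
            focal = focal, direction = direction, total = total)
}

#' @export
print.tally_table <- function(x, ...) {
  cat(sprintf("Tally (%s) for %s; total %d\n", attr(x, "direction"),
              paste(attr(x, "focal"), collapse = ","), attr(x, "total")))
  print.data.frame(cbind(as.data.frame(x),
                         display = format_percent(x$percent)), ...)
  invisible(x)
}

#' Tally a cell's synaptic inputs by presynaptic type
#'
#' Counts input records grouped by (folded) presynaptic type. AC inputs are
#' additionally split by compartment into an ON-layer row (distal dendrites)
#' and a soma row (soma plus proximal dendrites), the layout of published AII
#' input tables; the split rows' percentages are shares of the AC total,
#' other rows' of the direction total. Percentages are rounded half-up to one
#' decimal (display drops a trailing `.0`).
#'
#' @param cell focal postsynaptic skeleton id
#' @param tab synapse table ([build_synapse_table()] or a fixture)
#' @param split_ac split AC rows by compartment (default TRUE)
#' @param strict drop one-sided records first
#' @return a `tally_table` (data.frame: partner, count, percent)
#' @export
tally_inputs <- function(cell, tab, split_ac = TRUE, strict = FALSE) {
  if (strict) tab <- tab[tab$provenance %in% c("id-matched", "proximity"), ]
  rec <- tab[!is.na(tab$post_id) & tab$post_id %in% cell, ]
  total <- nrow(rec)
  ptype <- parent_cell_type(rec$pre_type)
  cnt <- table(factor(ptype, levels = unique(c("RB", "AC", sort(unique(ptype))))))
  rows <- data.frame(partner = names(cnt), count = as.integer(cnt),
                     stringsAsFactors = FALSE)
  rows$percent <- round_half_up(100 * rows$count / max(total, 1), 1)
  if (split_ac && any(ptype == "AC")) {
    ac <- rec[ptype == "AC", ]
    n_on <- sum(ac$compartment == "distal_dendrite")
    n_soma <- nrow(ac) - n_on  # soma + proximal + unassigned
    extra <- data.frame(
      partner = c("AC (ON layer)", "AC (Soma)"),
      count = c(n_on, n_soma),
      percent = round_half_up(100 * c(n_on, n_soma) / max(nrow(ac), 1), 1))
    at <- which(rows$partner == "AC")
    rows$partner[at] <- "AC (Total)"
    rows <- rbind(rows[seq_len(at), ], extra,
                  if (at < nrow(rows)) rows[(at + 1):nrow(rows), ])
  }
  new_tally(rows, cell, "input", total)
}

#' Tally output synapses of one or more cells by postsynaptic type
#'
#' Counts output records grouped by (folded) postsynaptic type, pooled over
#' the given presynaptic skeletons. Percentages are shares of the pooled
#' direction total under the same rounding rule as [tally_inputs()].
#'
#' @param cells presynaptic skeleton id(s), pooled
#' @param tab synapse table
#' @param strict drop one-sided records first
#' @return a `tally_table`
#' @export
tally_outputs <- function(cells, tab, strict = FALSE) {
  if (strict) tab <- tab[tab$provenance %in% c("id-matched", "proximity"), ]
  rec <- tab[!is.na(tab$pre_id) & tab$pre_id %in% cells, ]
  total <- nrow(rec)
  ptype <- parent_cell_type(rec$post_type)
  lev <- unique(c("AII", "RB", "ON_CB", sort(unique(ptype))))
  cnt <- table(factor(ptype, levels = lev))
  rows <- data.frame(partner = names(cnt), count = as.integer(cnt),
                     stringsAsFactors = FALSE)
  rows$percent <- round_half_up(100 * rows$count / max(total, 1), 1)
  new_tally(rows, cells, "output", total)
}

#' Mean and SD of tally rows across cells
#'
#' Row-wise arithmetic mean and sample (n - 1) standard deviation of counts
#' across two or more per-cell tallies with identical row keys; the `disp`
#' column renders the published "mean ± SD" convention (both rounded half-up
#' to integers). Raw values are retained.
#'
#' @param tables list of `tally_table`s with identical `partner` keys
#' @return data.frame(partner, mean, sd, disp)
#' @export
aggregate_summary <- function(tables) {
  if (length(tables) < 2) stopf("need >= 2 tables to aggregate")
  keys <- lapply(tables, function(t) t$partner)
  for (k in seq_along(keys)[-1])
    if (!identical(keys[[1]], keys[[k]]))
      stopf("tally row keys differ: {%s} vs {%s}",
            paste(keys[[1]], collapse = ","), paste(keys[[k]], collapse = ","))
  counts <- sapply(tables, function(t) t$count)
  m <- rowMeans(counts)
  s <- apply(counts, 1, stats::sd)
  data.frame(partner = keys[[1]], mean = m, sd = s,
             disp = sprintf("%d ± %d", as.integer(round_half_up(m)),
                            as.integer(round_half_up(s))),
             stringsAsFactors = FALSE)
}

#' Axon-to-target convergence
#'
#' Per-pair synapse counts between a presynaptic and a postsynaptic skeleton
#' group, with two summary means: total synapses divided by the number of
#' presynaptic skeletons (the convention behind "~130 synapses / 61 axons ~
#' 2 inputs per AII"), and divided by the number of connected pairs.
#'
#' @param pre_group,post_group skeleton id vectors
#' @param tab synapse table
#' @return list(pairs = data.frame(pre_id, post_id, n), total,
#'   mean_per_pre, mean_per_pair)
#' @export
convergence <- function(pre_group, post_group, tab) {
  rec <- tab[!is.na(tab$pre_id) & !is.na(tab$post_id) &
               tab$pre_id %in% pre_group & tab$post_id %in% post_group, ]
  if (nrow(rec)) {
    agg <- stats::aggregate(list(n = rec$synapse_id),
                            by = list(pre_id = rec$pre_id, post_id = rec$post_id),
                            FUN = length)
    agg <- agg[order(agg$pre_id, agg$post_id), ]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(pre_id = integer(), post_id = integer(), n = integer())
  }
  total <- sum(agg$n)
  list(pairs = agg, total = total,
       mean_per_pre = total / max(length(pre_group), 1),
       mean_per_pair = if (nrow(agg)) total / nrow(agg) else NA_real_)
}

#' Composition of rod bipolar dyads containing a focal amacrine type
#'
#' Ribbon records sharing a presynaptic cell are grouped into release sites by
#' single-linkage clustering at `dyad_radius_nm`. Sites with exactly two
#' postsynaptic partners, one of which is of the focal type, are classified by
#' the identity of the second partner: `AC+AII` (the focal AC replaces the
#' A17), `AC+A17` (it replaces the AII) or `AC+UNIDENTIFIED`. Sites with more
#' than two partners are flagged as triads and excluded from the percentages;
#' sites where only the focal partner was traced count as incomplete.
#'
#' @param rb_cells presynaptic (rod bipolar) skeleton ids
#' @param tab synapse table
#' @param focal_types postsynaptic types treated as the focal AC (default
#'   `NOS1_AC` and `AC`)
#' @param dyad_radius_nm linking radius (default 300)
#' @return list(counts, percent, n_dyads, n_triads, n_incomplete)
#' @export
dyad_composition <- function(rb_cells, tab,
                             focal_types = c("NOS1_AC", "AC"),
                             dyad_radius_nm = 300) {
  rec <- tab[tab$kind == "ribbon" & !is.na(tab$pre_id) &
               tab$pre_id %in% rb_cells, ]
  classes <- c("AC+AII", "AC+A17", "AC+UNIDENTIFIED")
  counts <- stats::setNames(integer(3), classes)
  n_triads <- 0L; n_incomplete <- 0L
  for (pre in unique(rec$pre_id)) {
    r <- rec[rec$pre_id == pre, ]
    cl <- single_linkage_clusters(cbind(r$x_nm, r$y_nm, r$z_nm), dyad_radius_nm)
    for (g in split(seq_len(nrow(r)), cl)) {
      partners <- r$post_type[g]
      if (length(g) > 2) { n_triads <- n_triads + 1L; next }
      is_focal <- partners %in% focal_types
      if (!any(is_focal)) next
      if (length(g) == 1) { n_incomplete <- n_incomplete + 1L; next }
      other <- partners[which(!is_focal)[1]]
      if (all(is_focal)) other <- "UNIDENTIFIED"  # two focal marks: ambiguous
      key <- switch(parent_cell_type(other), AII = "AC+AII", A17 = "AC+A17",
                    "AC+UNIDENTIFIED")
      counts[key] <- counts[key] + 1L
    }
  }
  n <- sum(counts)
  list(counts = counts,
       percent = round_half_up(100 * counts / max(n, 1), 1),
       n_dyads = n, n_triads = n_triads, n_incomplete = n_incomplete)
}

# single-linkage cluster labels at a linking radius (positions in the
# radius' units); hand-rolled union-find so stats::hclust can stay an
# independent oracle in the tests
single_linkage_clusters <- function(pos, radius) {
  n <- nrow(pos)
  if (n == 1) return(1L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((pos[i, ] - pos[j, ])^2)) <= radius) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Export / import a synapse table as TSV
#'
#' @param tab synapse table
#' @param path TSV path
#' @return `path` / the table
#' @export
write_synapse_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_synapse_tsv
#' @export
read_synapse_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
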