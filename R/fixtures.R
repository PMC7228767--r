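#' Published per-cell connectivity counts used as fixture inputs
#'
#' `table1_counts()`: inputs to three fully annotated AII amacrine cells (rod
#' bipolar ribbon inputs; conventional AC inputs split into ON-layer and
#' soma/proximal compartments). `table2_counts()`: connectivity of the
#' amacrine population presynaptic to AIIs — 61 partially reconstructed
#' axons pooled, plus two complete cells. These printed counts are inputs to
#' the tally/summary machinery, which recomputes all percentages and
#' mean ± SD values from them.
#'
#' @return named numeric structures of per-cell counts
#' @export
table1_counts <- function() {
  m <- cbind(`AII_1` = c(173, 161, 17), `AII_2` = c(171, 157, 20),
             `AII_3` = c(176, 161, 15))
  rownames(m) <- c("RB", "AC_ON_layer", "AC_soma")
  m
}

#' @rdname table1_counts
#' @export
table2_counts <- function() {
  list(
    axons = list(inputs = c(RB = 1, ON_CB = 1),
                 outputs = c(AII = 1212, RB = 173, ON_CB = 35, UNIDENTIFIED = 5)),
    cell1 = list(inputs = c(AC = 200, RB = 47, ON_CB = 66, UNIDENTIFIED = 2),
                 outputs = c(AII = 93, RB = 11, ON_CB = 11)),
    cell2 = list(inputs = c(AC = 183, RB = 56, ON_CB = 55, UNIDENTIFIED = 3),
                 outputs = c(AII = 86, RB = 18, ON_CB = 2)))
}

fixture_row <- function(n, pre_id, pre_type, post_id, post_type, kind,
                        compartment, depth = NA_real_, x0 = 0) {
  if (n == 0) return(empty_synapse_table()[0, ])
  data.frame(synapse_id = NA_integer_,
             pre_id = rep_len(pre_id, n), pre_type = pre_type,
             post_id = rep_len(post_id, n), post_type = post_type,
             kind = kind, x_nm = x0 + seq_len(n) * 1000, y_nm = 0, z_nm = 0,
             depth = depth, compartment = compartment, provenance = "fixture",
             pre_node = NA_integer_, post_node = NA_integer_,
             kind_flag = FALSE, stringsAsFactors = FALSE)
}

#' Synapse-record fixtures encoding the published tables
#'
#' Expands the printed per-cell counts into synapse-record tables shaped like
#' [build_synapse_table()] output, so that the tally, summary, convergence
#' and dyad operations can be exercised against every printed number. Ids:
#' AIIs 1–3, complete cells 201–202, axons 101–161, rod bipolars 300+,
#' other/unnamed partner cells 900+.
#'
#' @return list(aii_inputs, axon_outputs, cell_outputs, cell_inputs,
#'   convergence, dyads) of synapse tables
#' @export
table_fixtures <- function() {
  t1 <- table1_counts(); t2 <- table2_counts()
  # Table 1: per-AII input records (one-sided, observer-marked)
  aii <- do.call(rbind, lapply(1:3, function(j) {
    rbind(fixture_row(t1["RB", j], 300 + j, "RB", j, "AII", "ribbon",
                      "distal_dendrite", depth = 1.2),
          fixture_row(t1["AC_ON_layer", j], 400 + j, "AC", j, "AII",
                      "conventional", "distal_dendrite", depth = 1.2),
          fixture_row(t1["AC_soma", j], 500 + j, "AC", j, "AII",
                      "conventional", "soma", depth = -0.2))
  }))
  # Table 2, pooled axon outputs: 61 presynaptic axons (ids 101..161)
  expand_out <- function(counts, pre_ids, post_base) {
    do.call(rbind, lapply(names(counts), function(ty)
      fixture_row(counts[[ty]], pre_ids, "AC",
                  post_base[[ty]] + seq_len(max(counts[[ty]], 1)) %% 97, ty,
                  "conventional", "distal_dendrite", depth = 1.2)))
  }
  post_base <- list(AII = 900, RB = 1100, ON_CB = 1300, UNIDENTIFIED = 1400)
  axon_out <- expand_out(t2$axons$outputs, 101:161, post_base)
  cell_out <- rbind(expand_out(t2$cell1$outputs, 201, post_base),
                    expand_out(t2$cell2$outputs, 202, post_base))
  cell_in <- do.call(rbind, lapply(c(1, 2), function(k) {
    cnt <- t2[[paste0("cell", k)]]$inputs
    do.call(rbind, lapply(names(cnt), function(ty)
      fixture_row(cnt[[ty]], 1500 + seq_len(max(cnt[[ty]], 1)), ty, 200 + k,
                  "NOS1_AC", if (ty %in% bipolar_types()) "ribbon" else "conventional",
                  "unassigned")))
  }))
  # the ~130 synapses the 61 axons make onto the three reconstructed AIIs
  conv <- fixture_row(130, 101:161, "AC", c(1, 2, 3), "AII", "conventional",
                      "distal_dendrite", depth = 1.2)
  # 100 rod-bipolar dyads containing the focal AC: 75 / 18 / 7
  dyad_one <- function(m, partner_type) {
    x <- m * 5000
    rbind(fixture_row(1, 300 + m, "RB", 201, "NOS1_AC", "ribbon",
                      "distal_dendrite", depth = 1.2, x0 = x),
          fixture_row(1, 300 + m, "RB", 600 + m, partner_type, "ribbon",
                      "distal_dendrite", depth = 1.2, x0 = x + 100))
  }
  cls <- rep(c("AII", "A17", "UNIDENTIFIED"), c(75, 18, 7))
  dyads <- do.call(rbind, lapply(seq_along(cls), function(m)
    dyad_one(m, cls[m])))
  fix <- list(aii_inputs = aii, axon_outputs = axon_out,
              cell_outputs = cell_out, cell_inputs = cell_in,
              convergence = conv, dyads = dyads)
  fix <- lapply(fix, function(df) { df$synapse_id <- seq_len(nrow(df)); df })
  fix
}
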