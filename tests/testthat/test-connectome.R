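make_two_cell_forest <- function(out_comment, in_comment, dist_nm = 100) {
  sc <- voxel_scale(1, 1, 1)  # 1 nm voxels for easy arithmetic
  a <- skeleton(3, "AC_3",
                nodes = data.frame(node_id = 1:2, x = c(0, 0), y = 0,
                                   z = c(0, 1000),
                                   comment = c(NA, out_comment)),
                edges = data.frame(source = 1, target = 2))
  b <- skeleton(7, "AII_7",
                nodes = data.frame(node_id = 3:4, x = c(dist_nm, dist_nm),
                                   y = 0, z = c(1000, 2000),
                                   comment = c(in_comment, NA)),
                edges = data.frame(source = 3, target = 4))
  f <- skeleton_forest(list(a, b), sc)
  anns <- rbind(parse_node_annotations(a$nodes, 3L, annotation_pattern()),
                parse_node_annotations(b$nodes, 7L, annotation_pattern()))
  f$annotations <- anns
  f
}

test_that("id-matched annotations collapse to a single two-sided record", {
  f <- make_two_cell_forest("syn:conv:out:AII:7", "syn:conv:in:AC:3")
  tab <- build_synapse_table(f)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$pre_id, 3L)
  expect_equal(tab$post_id, 7L)
  expect_equal(tab$kind, "conventional")
  expect_equal(tab$provenance, "id-matched")
  # record position is the midpoint of the two marks
  expect_equal(tab$x_nm, 50)
})

test_that("unpaired marks become one-sided records; distant marks do not pair", {
  f <- make_two_cell_forest("syn:conv:out:AII", "syn:conv:in:AC", dist_nm = 2000)
  tab <- build_synapse_table(f)   # no ids, 2 um apart: > epsilon
  expect_equal(sort(tab$provenance), c("post-only", "pre-only"))
  # same marks within epsilon pair by proximity
  f <- make_two_cell_forest("syn:conv:out:AII", "syn:conv:in:AC", dist_nm = 300)
  tab <- build_synapse_table(f)
  expect_equal(tab$provenance, "proximity")
  # a larger epsilon rescues the distant pair
  f <- make_two_cell_forest("syn:conv:out:AII", "syn:conv:in:AC", dist_nm = 2000)
  tab <- build_synapse_table(f, pairing = list(epsilon_nm = 5000))
  expect_equal(tab$provenance, "proximity")
})

test_that("mutually declared partners with incompatible kinds are a conflict", {
  f <- make_two_cell_forest("syn:conv:out:AII:7", "syn:ribbon:in:AC:3")
  expect_error(build_synapse_table(f), "conflicting kinds")
})

test_that("ribbon records from non-bipolar presynaptic cells are flagged, not dropped", {
  f <- make_two_cell_forest("syn:ribbon:out:AII:7", "syn:ribbon:in:AC:3")
  tab <- build_synapse_table(f)
  expect_equal(nrow(tab), 1)
  expect_true(tab$kind_flag)  # AC making a ribbon is anatomically suspect
})

test_that("pairing recovers the generator's true pairs", {
  gen <- generate_connectome(mini_params(seed = 21))
  fr <- truth_frame(gen$truth)
  # with ids: exact recovery
  tab <- build_synapse_table(gen$forest, fr, gen$truth$types)
  truth <- gen$truth$pairings
  key <- function(pre, pn, post, qn) paste(pre, pn, post, qn)
  got <- key(tab$pre_id, tab$pre_node, tab$post_id, tab$post_node)
  expect_true(all(key(truth$pre_id, truth$pre_node, truth$post_id,
                      truth$post_node) %in% got))
  expect_equal(nrow(tab), nrow(truth))
  # blind proximity pairing at the default epsilon: >= 99 %
  tab2 <- build_synapse_table(gen$forest, fr, gen$truth$types,
                              pairing = list(use_ids = FALSE))
  got2 <- key(tab2$pre_id, tab2$pre_node, tab2$post_id, tab2$post_node)
  frac <- mean(key(truth$pre_id, truth$pre_node, truth$post_id,
                   truth$post_node) %in% got2)
  expect_gte(frac, 0.99)
})

test_that("compartments: soma by geodesic radius, distal by depth", {
  gen <- generate_connectome(mini_params(seed = 22))
  fr <- truth_frame(gen$truth)
  tab <- build_synapse_table(gen$forest, fr, gen$truth$types)
  aii <- gen$truth$aii_ids[1]
  onto <- tab[!is.na(tab$post_id) & tab$post_id == aii, ]
  dac_in <- onto[onto$pre_type == "DAC", ]
  expect_true(all(dac_in$compartment == "soma"))
  conv_in <- onto[onto$pre_type == "AC", ]
  expect_true(all(conv_in$compartment == "distal_dendrite"))
  # and no AC input lands between the SAC planes
  expect_equal(sum(assign_laminar_zone(onto$depth[onto$kind == "conventional"])
                   == "between_SAC"), 0)
})

test_that("input tallies reproduce the printed per-AII table", {
  fix <- table_fixtures()
  t2 <- tally_inputs(2, fix$aii_inputs)
  expect_equal(t2$count[t2$partner == "RB"], 171)
  expect_equal(t2$count[t2$partner == "AC (Total)"], 177)
  expect_equal(t2$count[t2$partner == "AC (ON layer)"], 157)
  expect_equal(t2$count[t2$partner == "AC (Soma)"], 20)
  # ON-layer share of the AC total: 157/177 -> 89 %
  expect_equal(round_half_up(100 * 157 / 177), 89)
  expect_equal(round_half_up(t2$percent[t2$partner == "AC (ON layer)"]), 89)
  t3 <- tally_inputs(3, fix$aii_inputs)
  expect_equal(round_half_up(100 * t3$count[t3$partner == "AC (ON layer)"] /
                               t3$count[t3$partner == "AC (Total)"]), 91)
  # empty cell: all-zero table
  t0 <- tally_inputs(999, fix$aii_inputs)
  expect_equal(attr(t0, "total"), 0)
  expect_true(all(t0$count == 0))
})

test_that("output tallies reproduce the pooled-axon and per-cell printed shares", {
  fix <- table_fixtures()
  pooled <- tally_outputs(101:161, fix$axon_outputs)
  expect_equal(attr(pooled, "total"), 1425)
  expect_equal(pooled$count[pooled$partner == "AII"], 1212)
  expect_equal(round_half_up(100 * 1212 / 1425), 85)
  expect_equal(pooled$count[pooled$partner == "RB"], 173)
  expect_equal(round_half_up(100 * 173 / 1425), 12)
  cell2 <- tally_outputs(202, fix$cell_outputs)
  expect_equal(attr(cell2, "total"), 106)
  expect_equal(cell2$count[cell2$partner == "RB"], 18)
  expect_equal(round_half_up(cell2$percent[cell2$partner == "RB"]), 17)
  # single-record table: 100 %
  single <- fix$axon_outputs[1, ]
  t1 <- tally_outputs(single$pre_id, single)
  expect_equal(t1$percent[t1$count == 1], 100)
})

test_that("percentages sum to 100 within rounding slack", {
  fix <- table_fixtures()
  for (tl in list(tally_outputs(101:161, fix$axon_outputs),
                  tally_outputs(201, fix$cell_outputs),
                  tally_inputs(1, fix$aii_inputs))) {
    main <- tl[!grepl("layer|Soma", tl$partner), ]
    expect_lte(abs(sum(main$percent) - 100), nrow(main) * 0.1)
  }
})

test_that("subtype labels fold into their parents in tallies", {
  tab <- empty_synapse_table()
  tab <- rbind(tab, data.frame(synapse_id = 1:3, pre_id = 9L, pre_type = "AC",
                               post_id = c(1L, 2L, 3L),
                               post_type = c("ON_CB6", "ON_CB5", "ON_CB"),
                               kind = "conventional", x_nm = 0, y_nm = 0,
                               z_nm = 0, depth = NA_real_,
                               compartment = "unassigned", provenance = "fixture",
                               pre_node = NA_integer_, post_node = NA_integer_,
                               kind_flag = FALSE))
  tl <- tally_outputs(9, tab)
  expect_equal(tl$count[tl$partner == "ON_CB"], 3)
})

test_that("aggregate_summary reproduces the printed mean +/- SD rows", {
  fix <- table_fixtures()
  tl <- lapply(1:3, tally_inputs, tab = fix$aii_inputs)
  s <- aggregate_summary(tl)
  expect_equal(s$disp[s$partner == "RB"], "173 ± 3")
  expect_equal(s$disp[s$partner == "AC (Total)"], "177 ± 1")
  expect_equal(s$disp[s$partner == "AC (ON layer)"], "160 ± 2")
  expect_equal(s$disp[s$partner == "AC (Soma)"], "17 ± 3")
  # identical tables: SD 0; mismatched keys: error
  expect_equal(aggregate_summary(list(tl[[1]], tl[[1]]))$sd,
               rep(0, nrow(tl[[1]])))
  other <- tally_outputs(101, fix$axon_outputs)
  expect_error(aggregate_summary(list(tl[[1]], other)), "keys differ")
})

test_that("convergence matches brute-force enumeration and both conventions", {
  fix <- table_fixtures()
  cv <- convergence(101:161, 1:3, fix$convergence)
  expect_equal(cv$total, 130)
  expect_equal(cv$mean_per_pre, 130 / 61)
  expect_equal(round_half_up(cv$mean_per_pre), 2)
  # 3 axons, 1 synapse each: mean 1 under both conventions
  t3 <- fix$convergence[1:3, ]
  t3$pre_id <- 1:3 + 1000L; t3$post_id <- 1:3 + 2000L
  cv3 <- convergence(1001:1003, 2001:2003, t3)
  expect_equal(cv3$mean_per_pre, 1)
  expect_equal(cv3$mean_per_pair, 1)
  # random bipartite instance vs brute force
  set.seed(13)
  n <- 400
  tab <- fix$convergence[rep(1, n), ]
  tab$synapse_id <- seq_len(n)
  tab$pre_id <- sample(1:50, n, replace = TRUE)
  tab$post_id <- sample(301:350, n, replace = TRUE)
  cv <- convergence(1:50, 301:350, tab)
  brute <- table(paste(tab$pre_id, tab$post_id))
  expect_equal(sort(as.integer(cv$pairs$n)), sort(as.integer(brute)))
  expect_equal(cv$total, n)
  expect_equal(cv$mean_per_pair, n / length(brute))
})

test_that("dyad composition classifies second partners and flags triads", {
  fix <- table_fixtures()
  dc <- dyad_composition(301:400, fix$dyads)
  expect_equal(unname(dc$counts), c(75, 18, 7))
  expect_equal(unname(dc$percent), c(75, 18, 7))
  # single dyad: 100 / 0 / 0
  one <- fix$dyads[fix$dyads$pre_id == 301, ]
  dc1 <- dyad_composition(301, one)
  expect_equal(unname(dc1$percent), c(100, 0, 0))
  # a third partner within the dyad radius makes a triad, excluded
  tri <- rbind(one, transform(one[2, ], post_id = 999L, post_type = "GC",
                              x_nm = x_nm + 50))
  dct <- dyad_composition(301, tri)
  expect_equal(dct$n_triads, 1)
  expect_equal(dct$n_dyads, 0)
})

test_that("conservation: outputs counted on A equal inputs counted on B", {
  gen <- generate_connectome(mini_params(seed = 30))
  fr <- truth_frame(gen$truth)
  tab <- build_synapse_table(gen$forest, fr, gen$truth$types)
  two_sided <- tab[tab$provenance %in% c("id-matched", "proximity"), ]
  ax <- gen$truth$axon_ids; aii <- gen$truth$aii_ids
  n_out <- sum(two_sided$pre_id %in% ax & two_sided$post_id %in% aii)
  n_in <- sum(two_sided$post_id %in% aii & two_sided$pre_id %in% ax)
  expect_equal(n_out, n_in)
  # tally totals invariant under record permutation
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(attr(tally_outputs(ax, perm), "total"),
               attr(tally_outputs(ax, tab), "total"))
})

test_that("synapse tables round-trip through TSV", {
  gen <- generate_connectome(mini_params(seed = 31))
  tab <- build_synapse_table(gen$forest, truth_frame(gen$truth), gen$truth$types)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_synapse_tsv(tab, p)
  back <- read_synapse_tsv(p)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$pre_id, tab$pre_id)
  expect_equal(back$x_nm, tab$x_nm, tolerance = 1e-9)
})
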