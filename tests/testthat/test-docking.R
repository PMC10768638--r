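mk_point <- function(id, kind, x, y = 0, z = 0, side) {
  data.frame(id = id, kind = kind, x = x, y = y, z = z, side = side,
             stringsAsFactors = FALSE)
}

test_that("contact enumeration follows the potential table", {
  p <- mk_point("P1", "HD", 0, side = "protein")
  l <- mk_point("l1", "HA", 1, side = "ligand")
  tab <- data.frame(protein_kind = "HD", ligand_kind = "HA", weight = 1.0)
  ct <- enumerate_contacts(p, l, tab)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$weight, 1.0)
  # kind pairs absent from the table produce no vertex
  l2 <- mk_point("l2", "AR", 2, side = "ligand")
  expect_equal(nrow(enumerate_contacts(p, l2, tab)), 0L)
  # all-pairs table: 4 x 6 points -> 24 contact vertices
  prot <- do.call(rbind, lapply(1:4, function(i) {
    mk_point(paste0("P", i), "HD", i, side = "protein")
  }))
  lig <- do.call(rbind, lapply(1:6, function(i) {
    mk_point(paste0("l", i), "HA", -i, side = "ligand")
  }))
  expect_equal(nrow(enumerate_contacts(prot, lig, tab)), 24L)
  expect_error(enumerate_contacts(mk_point("P1", "XX", 0, side = "protein"),
                                  l, tab), "unknown pharmacophore kind")
  expect_error(enumerate_contacts(l, l, tab), "ligand points")
})

test_that("edge compatibility implements the tau + 2*epsilon band", {
  tab <- data.frame(protein_kind = "HD", ligand_kind = "HA", weight = 1)
  # protein points 3 apart, ligand points d apart; all kind pairs allowed so
  # the 4 contacts are rows (P1,l1), (P1,l2), (P2,l1), (P2,l2)
  mk_case <- function(d) {
    prot <- rbind(mk_point("P1", "HD", 0, side = "protein"),
                  mk_point("P2", "HD", 3, side = "protein"))
    lig <- rbind(mk_point("l1", "HA", 10, side = "ligand"),
                 mk_point("l2", "HA", 10 + d, side = "ligand"))
    enumerate_contacts(prot, lig, tab)
  }
  rule <- flexibility_rule(tau = 1, epsilon = 0.5)
  ct <- mk_case(3)  # D_L = D_P
  # contacts (P1,l1) and (P2,l2) share nothing: compatible for any tau,eps
  expect_true(compatible_edge(ct[1, ], ct[4, ], flexibility_rule(0, 0)))
  # exclusivity: contacts sharing a point are never compatible
  expect_false(compatible_edge(ct[1, ], ct[3, ], rule))  # share l1
  expect_false(compatible_edge(ct[1, ], ct[2, ], rule))  # share P1
  # inclusive boundary at |D_L - D_P| = tau + 2 eps; just beyond fails
  ct_edge <- mk_case(3 + 2)      # |D_L - D_P| = 2 = 1 + 2*0.5
  expect_true(compatible_edge(ct_edge[1, ], ct_edge[4, ], rule))
  ct_out <- mk_case(3 + 2.01)
  expect_false(compatible_edge(ct_out[1, ], ct_out[4, ], rule))
})

test_that("per-kind flexibility with equal entries reproduces the constant rule", {
  fx <- rigid_complex(n_true_contacts = 5, n_decoys = 4, noise_A = 0.3,
                      seed = 31)
  const_rule <- flexibility_rule(tau = 1, epsilon = 0.5)
  kinds <- c(HA = 1, HD = 1, NC = 1, AR = 1)
  per_kind <- flexibility_rule(tau = kinds * 1, epsilon = kinds * 0.5)
  b1 <- build_big(fx$protein, fx$ligand, rule = const_rule)
  b2 <- build_big(fx$protein, fx$ligand, rule = per_kind)
  expect_identical(b1$graph$A, b2$graph$A)
  expect_equal(b1$graph$omega, b2$graph$omega)
})

test_that("BIG construction yields valid weighted graphs and poses", {
  # a single contact gives a one-vertex graph
  p <- mk_point("P1", "HD", 0, side = "protein")
  l <- mk_point("l1", "HA", 1, side = "ligand")
  big <- build_big(p, l)
  expect_equal(big$graph$N, 1L)
  expect_equal(sum(big$graph$A), 0)
  # two geometrically consistent contacts form K2
  prot <- rbind(mk_point("P1", "HD", 0, side = "protein"),
                mk_point("P2", "HA", 4, side = "protein"))
  lig <- rbind(mk_point("l1", "HA", 20, side = "ligand"),
               mk_point("l2", "HD", 24, side = "ligand"))
  big <- build_big(prot, lig)
  true_vertices <- which(big$legend$protein_id == "P1" &
                           big$legend$ligand_id == "l1" |
                           big$legend$protein_id == "P2" &
                           big$legend$ligand_id == "l2")
  expect_equal(big$graph$A[true_vertices[1], true_vertices[2]], 1)
  # empty contact set warns but returns a valid empty graph
  expect_warning(big0 <- build_big(p, mk_point("l9", "AR", 0, side = "ligand")),
                 "empty")
  expect_equal(big0$graph$N, 0L)
  # pose readout round-trips the legend
  pose <- clique_to_pose(c(true_vertices[1], true_vertices[2]), big$legend)
  expect_setequal(pose$protein_id, c("P1", "P2"))
  expect_match(pose$label[1], "^\\(")
  expect_equal(nrow(clique_to_pose(integer(0), big$legend)), 0L)
  expect_error(clique_to_pose(99L, big$legend), "legend")
})

test_that("rigid synthetic complexes are solved exactly by the clique pipeline", {
  for (s in 1:20) {
    fx <- rigid_complex(n_true_contacts = sample(4:7, 1),
                        n_decoys = sample(0:5, 1), noise_A = 0, seed = 600 + s)
    big <- build_big(fx$protein, fx$ligand)
    best <- max_weighted_clique_exact(big$graph)
    pose <- clique_to_pose(best, big$legend)
    expect_setequal(paste(pose$protein_id, pose$ligand_id),
                    paste(fx$true_contacts$protein_id,
                          fx$true_contacts$ligand_id))
  }
})

test_that("true contacts survive sub-threshold coordinate noise", {
  rule <- flexibility_rule(tau = 1, epsilon = 0.5)
  for (s in 1:5) {
    fx <- rigid_complex(n_true_contacts = 5, n_decoys = 3, noise_A = 0.1,
                        seed = 700 + s)
    big <- build_big(fx$protein, fx$ligand, rule = rule)
    truth <- which(paste(big$legend$protein_id, big$legend$ligand_id) %in%
                     paste(fx$true_contacts$protein_id,
                           fx$true_contacts$ligand_id))
    expect_true(gbsgraph:::is_clique(big$graph, truth))
  }
})

test_that("binding interaction graphs satisfy the encoder's preconditions", {
  fx <- rigid_complex(n_true_contacts = 4, n_decoys = 3, noise_A = 0.2,
                      seed = 33)
  big <- build_big(fx$protein, fx$ligand)
  # constructor invariants already checked; encode end-to-end
  circ <- encode_graph(big$graph, choose_scaling(big$graph,
                                                 lambda_max_target = 0.9))
  expect_true(all(tanh(circ$r) < 1))
  expect_lt(max(abs(circuit_sampling_matrix(circ) -
                      laplacian_rescale(big$graph, circ$scaling))), 1e-8)
})
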