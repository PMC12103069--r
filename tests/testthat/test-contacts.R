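# Contact extraction, interface residues and metal sites

test_that("minimum residue distance matches brute force and breaks ties by name", {
  at <- function(x, y, z, name = "CA") {
    data.frame(elety = name, x = x, y = y, z = z, stringsAsFactors = FALSE)
  }
  same <- do.call(rbind, list(at(0, 0, 0, "N"), at(1, 1, 0, "CA")))
  expect_equal(min_residue_distance(same, same)$dist, 0)

  expect_equal(min_residue_distance(at(0, 0, 0), at(3, 4, 0))$dist, 5)

  set.seed(7)
  for (rep in 1:25) {
    a <- data.frame(elety = paste0("A", 1:8), x = rnorm(8, 0, 4),
                    y = rnorm(8, 0, 4), z = rnorm(8, 0, 4))
    b <- data.frame(elety = paste0("B", 1:6), x = rnorm(6, 3, 4),
                    y = rnorm(6, 0, 4), z = rnorm(6, 0, 4))
    expect_equal(min_residue_distance(a, b)$dist, brute_min_dist(a, b),
                 tolerance = 1e-12)
  }

  # exact tie: two atom pairs at the same distance -> lexicographic winner
  a <- rbind(at(0, 0, 0, "CB"), at(0, 0, 0, "CA"))
  b <- rbind(at(1, 0, 0, "OD"), at(1, 0, 0, "N"))
  m <- min_residue_distance(a, b)
  expect_identical(c(m$atom_a, m$atom_b), c("CA", "N"))

  expect_error(min_residue_distance(a[0, ], b), "no heavy atoms")
})

test_that("engineered contacts are recovered exactly, inclusively at the cutoff", {
  pc <- data.frame(pos_a = c(2, 5, 5, 9), pos_b = c(3, 1, 7, 10),
                   dist = c(3.5, 3.5, 3.9, 4.0))
  mc <- make_complex(synthetic_complex_spec(10, 10, planted_contacts = pc,
                                            seed = 11))
  cmap <- interface_contacts(mc$model, "A", "B", cutoff = 4.0)
  got <- cmap$contacts[, c("resno_a", "resno_b")]
  want <- pc[order(pc$pos_a, pc$pos_b), c("pos_a", "pos_b")]
  expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
  # the pair engineered at exactly 4.0 A is included (inclusive cutoff)
  expect_true(any(got$resno_a == 9 & got$resno_b == 10))
  expect_equal(cmap$contacts$min_dist,
               pc$dist[order(pc$pos_a, pc$pos_b)], tolerance = 0.02)

  # distant chains give an empty map; unknown chains error
  far <- make_complex(synthetic_complex_spec(5, 5, seed = 2))
  expect_equal(nrow(interface_contacts(far$model, "A", "B")$contacts), 0L)
  expect_error(interface_contacts(far$model, "A", "C"), "unknown chain")
})

test_that("pruned scan equals the naive all-pairs oracle on random fixtures", {
  set.seed(2024)
  for (rep in 1:100) {
    k <- sample(0:4, 1)
    mc <- quick_complex(k = k, dist = runif(1, 2.5, 5.5), seed = rep,
                        len_a = sample(8:15, 1), len_b = sample(8:15, 1))
    cutoff <- runif(1, 3, 6)
    fast <- interface_contacts(mc$model, "A", "B", cutoff, method = "pruned")
    slow <- interface_contacts(mc$model, "A", "B", cutoff, method = "naive")
    expect_identical(fast$contacts, slow$contacts)
  }
})

test_that("contacts are monotone in cutoff and symmetric in chain roles", {
  mc <- quick_complex(k = 4, dist = 3.2, seed = 31)
  cuts <- c(2, 3.3, 4, 5.9)
  maps <- lapply(cuts, function(ct)
    interface_contacts(mc$model, "A", "B", ct)$contacts)
  for (k in seq_len(length(cuts) - 1)) {
    small <- paste(maps[[k]]$resno_a, maps[[k]]$resno_b)
    large <- paste(maps[[k + 1]]$resno_a, maps[[k + 1]]$resno_b)
    expect_true(all(small %in% large))
  }
  ab <- interface_contacts(mc$model, "A", "B", 4)$contacts
  ba <- interface_contacts(mc$model, "B", "A", 4)$contacts
  expect_equal(paste(ab$resno_a, ab$resno_b),
               paste(ba$resno_b, ba$resno_a)[order(ba$resno_b, ba$resno_a)])
  expect_equal(sort(ab$min_dist), sort(ba$min_dist), tolerance = 1e-12)
})

test_that("masked residues never appear in contacts", {
  set.seed(5)
  for (rep in 1:10) {
    mc <- quick_complex(k = 4, seed = 100 + rep)
    prof <- sample(c(40, 90), 15, replace = TRUE)
    m <- mc$model
    m$residues$plddt[m$residues$chain == "A"] <- prof
    m <- mask_low_confidence(m, 70)
    cc <- interface_contacts(m, "A", "B")$contacts
    expect_false(any(cc$resno_a %in% which(prof == 40)))
  }
})

test_that("interface residues are deduplicated and sorted", {
  empty <- interface_contacts(make_complex(
    synthetic_complex_spec(4, 4, seed = 1))$model, "A", "B")
  expect_equal(nrow(interface_residues(empty, "a")), 0L)

  cm <- fake_cmap("x", e3_pos = c(10, 10, 12), e2_pos = c(50, 52, 50))
  expect_equal(interface_residues(cm, "a")$resno, c(10, 12))
  expect_equal(interface_residues(cm, "b")$resno, c(50, 52))

  pc <- data.frame(pos_a = c(3, 3, 8), pos_b = c(2, 6, 9), dist = 3.5)
  mc <- make_complex(synthetic_complex_spec(10, 10, planted_contacts = pc,
                                            seed = 4))
  got <- interface_residues(interface_contacts(mc$model, "A", "B"), "a")
  expect_equal(got$resno, sort(unique(pc$pos_a)))
})

test_that("metal sites list coordinating atoms within the cutoff", {
  none <- make_complex(synthetic_complex_spec(5, 5, seed = 1))
  expect_length(detect_metal_sites(none$model), 0L)

  mc <- make_complex(synthetic_complex_spec(
    12, 5, zinc_sites = list(list(anchors = c(2, 5, 7, 9), dist = 2.3)),
    seed = 8))
  sites <- detect_metal_sites(mc$model, coordination_cutoff = 2.8)
  expect_length(sites, 1L)
  expect_false(sites[[1]]$unligated)
  expect_equal(nrow(sites[[1]]$ligands), 4L)
  expect_true(all(sites[[1]]$ligands$atom == "SG"))
  expect_true(all(sites[[1]]$ligands$resname == "CYS"))
  expect_equal(sites[[1]]$ligands$dist, rep(2.3, 4), tolerance = 1e-6)
  expect_true(!is.unsorted(sites[[1]]$ligands$dist))

  # an ion beyond the cutoff of everything is reported unligated
  m <- mc$model
  m$hetero_ions$x <- m$hetero_ions$x + 500
  far <- detect_metal_sites(m)
  expect_true(far[[1]]$unligated)
  expect_equal(nrow(far[[1]]$ligands), 0L)
})

test_that("contact TSV has the documented schema and 2-decimal distances", {
  mc <- quick_complex(k = 2, seed = 6)
  cmap <- interface_contacts(mc$model, "A", "B", complex_id = "toy")
  f <- tempfile(fileext = ".tsv")
  write_contacts_tsv(cmap, f)
  tab <- read.delim(f, comment.char = "#")
  expect_identical(names(tab),
                   c("complex_id", "chain_a", "resnum_a", "resname_a",
                     "chain_b", "resnum_b", "resname_b", "min_dist",
                     "atom_a", "atom_b", "a_backbone", "b_backbone"))
  expect_equal(nrow(tab), nrow(cmap$contacts))
  expect_true(all(grepl("^[0-9]+\\.[0-9]{2}$",
                        readLines(f)[-(1:3)] |> strsplit("\t") |>
                          vapply(`[`, "", 8))))
})
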