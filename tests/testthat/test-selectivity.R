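# Contact projection and canonical/common/selective classification

test_that("projection uses the identity for the reference and maps targets", {
  pmap <- identity_pmap("REF", "REF")
  cm <- fake_cmap("c1", e3_pos = c(5, 9), e2_pos = c(50, 60))
  pr <- project_contacts(cm, pmap, target = "REF")
  expect_equal(pr$keys$e2_ref_pos, c(50, 60))
  expect_equal(nrow(pr$unprojected), 0L)

  # map 108 (reference) -> 73 (target): a contact at 73 projects to 108
  map <- data.frame(ref_pos = c(100, 108), ref_aa = "F",
                    target_pos = c(65, 73), target_aa = "F")
  pmap2 <- structure(list(reference_id = "REF", maps = list(J2 = map)),
                     class = "position_map")
  cm2 <- fake_cmap("c2", e3_pos = 27, e2_pos = 73)
  pr2 <- project_contacts(cm2, pmap2, target = "J2")
  expect_equal(pr2$keys$e2_ref_pos, 108)

  # unmapped target position (insertion) lands in unprojected, not dropped
  cm3 <- fake_cmap("c3", e3_pos = c(27, 30), e2_pos = c(73, 99))
  pr3 <- project_contacts(cm3, pmap2, target = "J2")
  expect_equal(nrow(pr3$keys), 1L)
  expect_equal(pr3$unprojected$resno_b, 99)

  expect_error(project_contacts(cm3, pmap2, target = "absent"),
               "does not cover")
})

test_that("classification matches the presence-matrix oracle on random panels", {
  canon <- toy_canon(e3 = c(5, 6, 7), e2 = c(50, 51, 52))
  set.seed(404)
  for (rep in 1:200) {
    n_complex <- sample(2:5, 1)
    ids <- paste0("cx", seq_len(n_complex))
    n_keys <- sample(1:10, 1)
    keys <- unique(data.frame(e3 = sample(1:12, n_keys, TRUE),
                              e2 = sample(45:56, n_keys, TRUE)))
    pres <- matrix(runif(nrow(keys) * n_complex) < 0.55,
                   nrow(keys), n_complex)
    # every key must exist somewhere
    none <- rowSums(pres) == 0
    pres[none, sample(n_complex, 1)] <- TRUE

    cmaps <- lapply(seq_len(n_complex), function(c_i) {
      sel <- pres[, c_i]
      fake_cmap(ids[c_i], keys$e3[sel], keys$e2[sel])
    })
    names(cmaps) <- ids
    pmap <- identity_pmap("REF", ids)
    cls <- classify_panel(cmaps, pmap, canon)

    ord <- match(paste(cls$keys$e3_pos, cls$keys$e2_ref_pos),
                 paste(keys$e3, keys$e2))
    want <- oracle_classes(pres[ord, , drop = FALSE],
                           keys$e3[ord], keys$e2[ord], canon)
    expect_identical(cls$keys$class, want)

    # partition: every key gets exactly one class, counts add up
    expect_equal(nrow(cls$keys), nrow(keys))
    expect_equal(sum(table(cls$keys$class)), nrow(keys))
    # selective keys are tagged with the complex that owns them
    sel_rows <- cls$keys$class == "selective"
    if (any(sel_rows)) {
      for (r in which(sel_rows)) {
        owner <- cls$keys$selective_for[r]
        expect_true(cls$keys[[paste0("present.", owner)]][r])
        expect_equal(cls$keys$n_present[r], 1L)
      }
    }
  }
})

test_that("panel order does not change classes; panels of one are rejected", {
  canon <- toy_canon()
  ids <- c("a", "b", "c")
  cmaps <- list(
    a = fake_cmap("a", c(5, 9, 11), c(50, 60, 61)),
    b = fake_cmap("b", c(5, 9), c(50, 60)),
    c = fake_cmap("c", c(5, 9, 12), c(50, 60, 62)))
  pmap <- identity_pmap("REF", ids)
  cls1 <- classify_panel(cmaps, pmap, canon)
  cls2 <- classify_panel(rev(cmaps), pmap, canon)
  k1 <- cls1$keys[order(cls1$keys$e3_pos, cls1$keys$e2_ref_pos),
                  c("e3_pos", "e2_ref_pos", "class", "selective_for")]
  k2 <- cls2$keys[order(cls2$keys$e3_pos, cls2$keys$e2_ref_pos),
                  c("e3_pos", "e2_ref_pos", "class", "selective_for")]
  expect_equal(k1, k2, ignore_attr = TRUE)

  expect_error(classify_panel(cmaps[1], pmap, canon), "at least 2")
})

test_that("removing a complex never turns another's selective key common", {
  canon <- toy_canon(e3 = 999, e2 = 999)   # no canonical interference
  set.seed(505)
  for (rep in 1:30) {
    ids <- paste0("cx", 1:4)
    keys <- unique(data.frame(e3 = sample(1:8, 6, TRUE),
                              e2 = sample(40:48, 6, TRUE)))
    pres <- matrix(runif(nrow(keys) * 4) < 0.5, nrow(keys), 4)
    pres[rowSums(pres) == 0, 1] <- TRUE
    cmaps <- lapply(1:4, function(i)
      fake_cmap(ids[i], keys$e3[pres[, i]], keys$e2[pres[, i]]))
    names(cmaps) <- ids
    pmap <- identity_pmap("REF", ids)
    full <- classify_panel(cmaps, pmap, canon)
    drop_id <- sample(ids, 1)
    reduced <- classify_panel(cmaps[setdiff(ids, drop_id)], pmap, canon)
    sel_full <- full$keys[full$keys$class == "selective" &
                          full$keys$selective_for != drop_id, ]
    if (nrow(sel_full)) {
      m <- match(paste(sel_full$e3_pos, sel_full$e2_ref_pos),
                 paste(reduced$keys$e3_pos, reduced$keys$e2_ref_pos))
      expect_false(any(reduced$keys$class[m] == "common" &
                       reduced$keys$n_present[m] < length(ids) - 1))
      expect_true(all(reduced$keys$class[m] == "selective"))
    }
  }
})

test_that("reports resolve residues per complex with deterministic layout", {
  empty <- structure(list(
    keys = data.frame(), complexes = character(0),
    projections = list(), unprojected = list()),
    class = "contact_classification")
  rep0 <- selectivity_report(empty)
  expect_equal(nrow(rep0), 0L)
  expect_true(all(c("complex_id", "class", "e3_pos") %in% names(rep0)))

  canon <- toy_canon()
  ids <- c("p", "q", "r")
  # q owns one unique key; everything else is shared by all
  cmaps <- list(p = fake_cmap("p", c(5, 9), c(50, 60)),
                q = fake_cmap("q", c(5, 9, 11), c(50, 60, 61)),
                r = fake_cmap("r", c(5, 9), c(50, 60)))
  cls <- classify_panel(cmaps, identity_pmap("REF", ids), canon)
  rep1 <- selectivity_report(cls)
  sel <- rep1[rep1$class == "selective", ]
  expect_equal(sel$complex_id, "q")
  expect_equal(sel$e3_pos, 11)
  expect_equal(sel$e2_ref_pos, 61)

  # all-common panel: no selective rows anywhere
  cm_common <- lapply(ids, function(i) fake_cmap(i, c(9, 10), c(60, 62)))
  names(cm_common) <- ids
  cls2 <- classify_panel(cm_common, identity_pmap("REF", ids), canon)
  expect_false(any(selectivity_report(cls2)$class == "selective"))

  f <- tempfile(fileext = ".tsv")
  write_classification_tsv(cls, f)
  tab <- read.delim(f, comment.char = "#")
  expect_equal(nrow(tab), nrow(cls$keys))
  expect_true(all(c("e3_pos", "e2_ref_pos", "class") %in% names(tab)))
})

test_that("the packaged canonical reference file has the documented landmarks", {
  canon <- canonical_reference()
  expect_true(all(24:28 %in% canon$e3_positions))
  expect_true(all(c(76, 79) %in% canon$e3_positions))
  expect_true(all(c(51, 54, 108) %in% canon$e2_reference_positions))
  expect_true(all(140:142 %in% canon$e2_reference_positions))
  # the E2-side positions carry the expected residues on the reference
  ws <- working_sequences()
  expect_identical(substr(ws[["UBE2E1"]], 140, 142), "SPA")
  expect_identical(substr(ws[["MuRF1_RM"]], 79, 79), "R")
  expect_identical(substr(ws[["MuRF1_RM"]], 76, 76), "P")
})
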