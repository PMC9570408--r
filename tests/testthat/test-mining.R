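test_that("fixture filtering reproduces the manifest exactly", {
  dir <- withr::local_tempdir()
  man <- make_mining_fixtures(dir, seed = 42)
  entries <- lapply(man$path, read_mining_entry)
  res <- filter_entries(entries)
  kept_ids <- vapply(res$kept, `[[`, "", "id")
  expect_setequal(kept_ids, man$id[man$keep])
  expect_setequal(res$rejects$id, man$id[!man$keep])
  rej <- merge(res$rejects, man[, c("id", "reason")], by = "id")
  # declared-covalent entries are rejected for their ligand, C-alpha
  # models for their protein, and so on
  expect_true(all(rej$reason.x == rej$reason.y |
                  (rej$reason.x == "no_noncovalent_ligand" &
                   rej$reason.y == "covalent")))
  # 2.9 A is kept (inclusive cutoff), 3.0 A is dropped
  expect_true("SYN2" %in% kept_ids)
  expect_false("SYN3" %in% kept_ids)
  # filtering is order-independent
  res2 <- filter_entries(rev(entries))
  expect_setequal(vapply(res2$kept, `[[`, "", "id"), kept_ids)
})

test_that("instances are extracted per ligand copy with translated names", {
  dir <- withr::local_tempdir()
  man <- make_mining_fixtures(dir, seed = 7)
  two_copy <- read_mining_entry(man$path[man$id == "SYN4"])
  inst <- extract_instances(two_copy)
  expect_length(inst, 2)
  expect_true(all(vapply(inst, `[[`, "", "species") == "NADH"))
  expect_true(all(c("O4'N", "C4A", "C1'N") %in% rownames(inst[[1]]$xyz)))
})

test_that("geometrically bonded ligands are detected as covalent", {
  dir <- withr::local_tempdir()
  man <- make_mining_fixtures(dir, seed = 1)
  entry <- read_mining_entry(man$path[man$id == "SYN1"])
  inst0 <- extract_instances(entry)
  expect_length(inst0, 1)
  # drag one ligand atom within 1.8 A of a polymer atom
  lig_row <- which(entry$atoms$label_comp_id == "NAD")[1]
  poly_row <- which(entry$atoms$group_PDB == "ATOM")[1]
  entry$atoms[lig_row, c("Cartn_x", "Cartn_y", "Cartn_z")] <-
    entry$atoms[poly_row, c("Cartn_x", "Cartn_y", "Cartn_z")] + 0.5
  expect_length(extract_instances(entry), 0)
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  dir <- withr::local_tempdir()
  man <- make_mining_fixtures(dir, seed = 1)
  entry <- read_mining_entry(man$path[man$id == "SYN1"])
  lig <- which(entry$atoms$label_comp_id == "NAD")
  # duplicate one ligand atom as a displaced altloc with lower occupancy
  row_a <- entry$atoms[lig[1], ]
  entry$atoms$label_alt_id[lig[1]] <- "A"
  entry$atoms$occupancy[lig[1]] <- 0.6
  row_b <- row_a
  row_b$label_alt_id <- "B"
  row_b$occupancy <- 0.4
  row_b$Cartn_x <- row_b$Cartn_x + 5
  entry$atoms <- rbind(entry$atoms, row_b)
  inst <- extract_instances(entry)
  expect_length(inst, 1)
  nm <- map_atom_names(row_a$label_atom_id, "component_to_paper", "NAD_plus")
  expect_equal(unname(inst[[1]]$xyz[nm, "x"]), row_a$Cartn_x)
})

test_that("mining metrics aggregate d with a direct mean/SD formula", {
  confs <- lapply(c(13, 14, 15), function(d) template_with_d("NAD_plus", d))
  inst <- lapply(seq_along(confs), function(k) {
    list(entry = paste0("E", k), instance = "inst", component = "NAD",
         species = "NAD_plus", xyz = confs[[k]]$xyz)
  })
  mt <- mine_metrics(inst)
  expect_equal(mt$d_mean, 14.0, tolerance = 1e-6)
  expect_equal(mt$d_sd, 1.0, tolerance = 1e-6)
  expect_equal(nrow(mt$table), 3)
  # single instance: mean is the value, SD undefined
  mt1 <- mine_metrics(inst[1])
  expect_equal(mt1$d_mean, 13, tolerance = 1e-6)
  expect_true(is.na(mt1$d_sd))
})

test_that("instances missing atoms are flagged per metric, not dropped", {
  conf <- build_template("NAD_plus")
  xyz <- conf$xyz[setdiff(rownames(conf$xyz), "N7N"), ]
  inst <- list(entry = "E", instance = "i", component = "NAD",
               species = "NAD_plus", xyz = xyz)
  row <- mine_metrics(list(inst))$table
  expect_true(is.na(row$theta))
  expect_false(is.na(row$d))
  expect_false(is.na(row$chi_N))
})

test_that("mined metrics reuse the geometry kernels exactly", {
  conf <- build_template("NADH", list(chi_N = -70, theta = 160))
  inst <- list(entry = "E", instance = "i", component = "NAI",
               species = "NADH", xyz = conf$xyz)
  row <- mine_metrics(list(inst))$table
  ref <- compute_metrics(conf)
  expect_equal(row$d, ref$d, tolerance = 1e-12)
  expect_equal(row$chi_N, ref$chi_N, tolerance = 1e-12)
  expect_equal(row$chi_A, ref$chi_A, tolerance = 1e-12)
  expect_equal(row$theta, ref$theta, tolerance = 1e-12)
  expect_equal(row$nu2, ref$nu2, tolerance = 1e-12)
})
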