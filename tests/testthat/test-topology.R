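test_that("atom counts match the five dinucleotide species", {
  expected <- c(NAD_plus = 70, NADH = 71, ox2_NAD = 70, ox4_NAD = 70,
                ox6_NAD = 70)
  for (sp in names(expected)) {
    top <- build_topology(sp)
    expect_equal(nrow(top$atoms), unname(expected[sp]), info = sp)
    expect_equal(nrow(top$atoms), length(unique(top$atoms$name)), info = sp)
  }
})

test_that("bond graph is connected and rings are complete", {
  for (sp in nad_species()) {
    top <- build_topology(sp)
    # connectivity: subtree from any atom with a non-existent bond removed
    reach <- nadfold:::subtree_atoms(top$bonds, "none", "none",
                                     top$atoms$name[1])
    expect_setequal(reach, top$atoms$name)
    expect_length(top$rings$nicotinamide, 6)
    expect_length(top$rings$adenine, 9)
    expect_true(all(unlist(top$rings) %in% top$atoms$name))
  }
})

test_that("every named dihedral is computable: atoms present, consecutive pairs bonded", {
  for (sp in nad_species()) {
    top <- build_topology(sp)
    bonded <- function(a, b) {
      any((top$bonds[, 1] == a & top$bonds[, 2] == b) |
          (top$bonds[, 1] == b & top$bonds[, 2] == a))
    }
    for (q in dihedral_definitions()) {
      expect_true(all(q %in% top$atoms$name), info = sp)
      expect_true(bonded(q[1], q[2]) && bonded(q[2], q[3]) &&
                  bonded(q[3], q[4]),
                  info = paste(sp, paste(q, collapse = "-")))
    }
  }
})

test_that("each ox species has exactly one extra carbonyl oxygen at the stated ring carbon", {
  carbonyl <- c(ox2_NAD = "C2N", ox4_NAD = "C4N", ox6_NAD = "C6N")
  nadh_ox <- grep("^O", build_topology("NADH")$atoms$name, value = TRUE)
  for (sp in names(carbonyl)) {
    top <- build_topology(sp)
    ox <- grep("^O", top$atoms$name, value = TRUE)
    extra <- setdiff(ox, nadh_ox)
    expect_length(extra, 1)
    partner <- top$bonds[top$bonds[, 1] == extra | top$bonds[, 2] == extra, ]
    expect_true(carbonyl[sp] %in% partner)
  }
})

test_that("rotatable-bond moving subtrees exclude the fixed side", {
  top <- build_topology("NAD_plus")
  for (nm in names(top$rotatable)) {
    rot <- top$rotatable[[nm]]
    expect_false(rot$bond[1] %in% rot$moving, info = nm)
    expect_true(rot$bond[2] %in% rot$moving, info = nm)
    expect_true(rot$dihedral[4] %in% rot$moving, info = nm)
    expect_false(rot$dihedral[1] %in% rot$moving, info = nm)
  }
  # chi_N moves the base, not the sugar
  expect_true(all(c("C2N", "C7N", "N7N") %in% top$rotatable$chi_N$moving))
  expect_false("C1'N" %in% top$rotatable$chi_N$moving)
})

test_that("atom-name map is bijective and round-trips", {
  for (sp in c("NAD_plus", "NADH")) {
    map <- atom_name_map(sp)
    expect_equal(anyDuplicated(map$component), 0)
    back <- map_atom_names(
      map_atom_names(map$paper, "paper_to_component", sp),
      "component_to_paper", sp)
    expect_identical(back, map$paper)
  }
  # ribose suffix conventions of the component dictionary
  expect_identical(map_atom_names("O4D", species = "NAD_plus"), "O4'N")
  expect_identical(map_atom_names("C1B", species = "NAD_plus"), "C1'A")
  expect_identical(
    map_atom_names(c("O4'N", "C4A"), "paper_to_component"),
    c("O4D", "C4A"))
})

test_that("unknown atom names raise an error listing the offenders", {
  expect_error(map_atom_names("NOPE", species = "NAD_plus"), "NOPE")
  expect_error(map_atom_names(c("C1B", "XX1"), species = "NAD_plus"), "XX1")
})

test_that("topology serializes to a readable plain-text file", {
  path <- withr::local_tempfile(fileext = ".top")
  write_topology_file(build_topology("NADH"), path)
  lines <- readLines(path)
  expect_true(any(grepl("NADH", lines)))
  expect_true(any(grepl("^C4N\tC\t", lines)))
})
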