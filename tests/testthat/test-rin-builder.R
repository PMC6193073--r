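test_that("minAtomDistance is the minimum over heavy-atom pairs", {
  s <- mkStructure(list(
    res1("A", 1, "ALA", 0),
    res1("A", 2, "GLY", 4.9),
    list(chain = "A", resno = 3, resname = "LEU",
         coords = rbind(c(0, 10, 10), c(10, 10, 10))),
    res1("A", 4, "VAL", 3, -6, 10)))
  expect_equal(minAtomDistance(s, "Ala1.A", "Gly2.A"), 4.9)
  # 3-4-5 triangle against the two-atom residue: min over pairs
  s2 <- mkStructure(list(
    list(chain = "A", resno = 1, resname = "ALA",
         coords = rbind(c(0, 0, 0), c(10, 0, 0))),
    res1("A", 2, "GLY", 3, 4, 0)))
  expect_equal(minAtomDistance(s2, "Ala1.A", "Gly2.A"), 5.0)
  # identical coordinates
  s3 <- mkStructure(list(res1("A", 1, "ALA", 1, 2, 3),
                         res1("B", 1, "GLY", 1, 2, 3)))
  expect_equal(minAtomDistance(s3, "Ala1.A", "Gly1.B"), 0.0)
  expect_error(minAtomDistance(s3, "Ala1.A", "Xxx9.Z"), "no atoms")
})

test_that("contact thresholds are strict-below and variant-dependent", {
  # r1 at 0, r2 at 4.9 (residue contact), water 3.4 from r1, 6+ from r2
  s <- mkStructure(list(
    res1("A", 1, "ALA", 0), res1("B", 1, "GLY", 4.9),
    res1("A", 100, "HOH", -3.4)))
  wet <- buildRIN(s, "wet")
  expect_setequal(paste(edgeTable(wet)$from, edgeTable(wet)$to),
                  c("Ala1.A Gly1.B", "Ala1.A Hoh100.A"))
  dry <- buildRIN(s, "dry")
  expect_equal(nrow(edgeTable(dry)), 1)
  expect_false(any(nodeTable(dry)$kind == "water"))
  # water at exactly 3.5: strictly "below" means no edge
  s35 <- mkStructure(list(
    res1("A", 1, "ALA", 0), res1("B", 1, "GLY", 4.9),
    res1("A", 100, "HOH", -3.5)))
  e35 <- edgeTable(buildRIN(s35, "wet"))
  expect_false("Hoh100.A" %in% c(e35$from, e35$to))
  # residue pair at exactly 5.0 is not in contact
  s50 <- mkStructure(list(res1("A", 1, "ALA", 0), res1("B", 1, "GLY", 5.0),
                          res1("A", 2, "CYS", 2)))
  e50 <- edgeTable(buildRIN(s50, "dry"))
  expect_false("Ala1.A Gly1.B" %in% paste(e50$from, e50$to))
  # uniform 3.5 A control: the 4.9 A residue contact disappears
  uni <- buildRIN(s, "wet_uniform")
  expect_setequal(paste(edgeTable(uni)$from, edgeTable(uni)$to),
                  "Ala1.A Hoh100.A")
  expect_equal(rinMetadata(uni)$thresholds$d_rr, 3.5)
  expect_error(buildRIN(s, "soaked"), "arg")
})

test_that("wet and dry RINs share the same residue-residue edge set", {
  s <- generateComplex(synthParams(nResPerChain = 12, nWaters = 25, seed = 3))
  wet <- buildRIN(s, "wet")
  dry <- buildRIN(s, "dry")
  waters <- nodeTable(wet)$label[nodeTable(wet)$kind == "water"]
  ew <- edgeTable(wet)
  rrWet <- ew[!(ew$from %in% waters) & !(ew$to %in% waters), ]
  expect_equal(rrWet, edgeTable(dry), ignore_attr = TRUE)
  # wet RIN is strictly denser when waters are present
  expect_gt(nrow(ew), nrow(edgeTable(dry)))
})

test_that("interface annotation is inclusive at 7 A and symmetric", {
  near <- mkStructure(list(res1("A", 1, "ALA", 0), res1("B", 1, "GLY", 6.9)))
  expect_setequal(annotateInterface(near, "A", "B"), c("Ala1.A", "Gly1.B"))
  at7 <- mkStructure(list(res1("A", 1, "ALA", 0), res1("B", 1, "GLY", 7.0)))
  expect_setequal(annotateInterface(at7, "A", "B"), c("Ala1.A", "Gly1.B"))
  far <- mkStructure(list(res1("A", 1, "ALA", 0), res1("B", 1, "GLY", 7.1)))
  expect_length(annotateInterface(far, "A", "B"), 0)
  apart <- mkStructure(list(res1("A", 1, "ALA", 0), res1("B", 1, "GLY", 50)))
  expect_length(annotateInterface(apart, "A", "B"), 0)
  # waters never define the interface
  wat <- mkStructure(list(res1("A", 1, "ALA", 0), res1("B", 1, "GLY", 20),
                          res1("A", 90, "HOH", 10)))
  expect_length(annotateInterface(wat, "A", "B"), 0)
  expect_error(annotateInterface(wat, "A", "Z"), "no protein residues")
})

test_that("interface waters are those adjacent to an interface residue", {
  # r1(A) and r2(B) 4 A apart -> interface; w1 touches r1, w2 touches only w1
  s <- mkStructure(list(
    res1("A", 1, "ALA", 0), res1("B", 1, "GLY", 4),
    res1("A", 100, "HOH", -3), res1("A", 101, "HOH", -6),
    res1("A", 102, "HOH", 30), res1("A", 103, "HOH", 33)))
  wet <- buildRIN(s, "wet", chainGroups = list("A", "B"))
  expect_setequal(interfaceWaters(wet), "Hoh100.A")
  # variant: only interface waters survive, water-water edges recomputed
  iw <- buildRIN(s, "interface_waters", chainGroups = list("A", "B"))
  expect_setequal(nodeTable(iw)$label[nodeTable(iw)$kind == "water"],
                  "Hoh100.A")
  # dry RIN has no interface waters
  expect_length(interfaceWaters(buildRIN(s, "dry")), 0)
  expect_error(buildRIN(s, "interface_waters"), "chainGroups")
})

test_that("interface_waters variant equals interfaceWaters applied to wet", {
  s <- generateComplex(synthParams(nResPerChain = 15, nWaters = 40, seed = 5))
  wet <- buildRIN(s, "wet", chainGroups = list("A", "B"))
  iw <- buildRIN(s, "interface_waters", chainGroups = list("A", "B"))
  expect_setequal(nodeTable(iw)$label[nodeTable(iw)$kind == "water"],
                  interfaceWaters(wet))
  # water-water edges among survivors are retained
  keep <- nodeTable(iw)$label
  ew <- edgeTable(wet)
  expect_equal(edgeTable(iw),
               ew[ew$from %in% keep & ew$to %in% keep, ],
               ignore_attr = TRUE)
})

test_that("water-node removal selectors behave as specified", {
  # waters with degrees 8, 5, 2 built from explicit edges
  nodes <- data.frame(
    label = c(sprintf("Res%d.A", 1:10), "Hoh1.A", "Hoh2.A", "Hoh3.A"),
    kind = c(rep("residue", 10), rep("water", 3)))
  e <- rbind(
    data.frame(from = "Hoh1.A", to = sprintf("Res%d.A", 1:8)),
    data.frame(from = "Hoh2.A", to = sprintf("Res%d.A", 1:5)),
    data.frame(from = "Hoh3.A", to = sprintf("Res%d.A", 1:2)),
    data.frame(from = "Res1.A", to = sprintf("Res%d.A", 2:10)))
  rin <- RIN(nodes, e, metadata = list(variant = "wet"))
  rm1 <- removeWaterNodes(rin, "max_degree")
  expect_setequal(rinMetadata(rm1)$waterRemoval$removed, "Hoh1.A")
  rm2 <- removeWaterNodes(rin, "degree_ge", k = 5)
  expect_setequal(rinMetadata(rm2)$waterRemoval$removed, c("Hoh1.A", "Hoh2.A"))
  rm3 <- removeWaterNodes(rin, "explicit", labels = "Hoh3.A")
  expect_setequal(rinMetadata(rm3)$waterRemoval$removed, "Hoh3.A")
  expect_false("Hoh3.A" %in% nodeTable(rm3)$label)
  # incident edges go with the node
  expect_false("Hoh1.A" %in% unlist(edgeTable(rm1)[c("from", "to")]))
  expect_error(removeWaterNodes(rin, "explicit", labels = "Res1.A"),
               "not water nodes")
  expect_error(removeWaterNodes(rin, "explicit", labels = "Hoh9.A"),
               "not water nodes")
  # max-degree ties resolve to the lexicographically first label
  tie <- RIN(nodes, rbind(
    data.frame(from = "Hoh2.A", to = sprintf("Res%d.A", 6:8)),
    data.frame(from = "Hoh1.A", to = sprintf("Res%d.A", 1:8)),
    data.frame(from = "Hoh3.A", to = sprintf("Res%d.A", 1:8))))
  expect_equal(rinMetadata(removeWaterNodes(tie, "max_degree"))$waterRemoval$removed,
               "Hoh1.A")
})

test_that("neighbor-pruned edge detection matches brute force all-pairs", {
  for (seed in 1:3) {
    s <- generateComplex(synthParams(nResPerChain = 10, nWaters = 30,
                                     seed = seed))
    a <- atomTable(s)
    expect_lte(nrow(a), 200)
    wet <- buildRIN(s, "wet")
    # brute force: all residue pairs, all atom pairs
    labs <- unique(a$label)
    kinds <- a$kind[match(labs, a$label)]
    expected <- character()
    for (i in seq_along(labs)[-length(labs)]) {
      for (j in (i + 1):length(labs)) {
        A <- as.matrix(a[a$label == labs[i], c("x", "y", "z")])
        B <- as.matrix(a[a$label == labs[j], c("x", "y", "z")])
        d <- sqrt(min(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)))
        cut <- if (kinds[i] == "water" || kinds[j] == "water") 3.5 else 5
        if (d < cut) {
          pair <- sort(c(labs[i], labs[j]))
          expected <- c(expected, paste(pair[1], pair[2]))
        }
      }
    }
    got <- paste(edgeTable(wet)$from, edgeTable(wet)$to)
    expect_setequal(got, expected)
  }
})

test_that("raising thresholds never removes an edge", {
  s <- generateComplex(synthParams(nResPerChain = 10, nWaters = 20, seed = 9))
  base <- buildRIN(s, "wet")
  wider <- buildRIN(s, "wet", contactThresholds(d_rr = 6, d_w = 4.2))
  expect_true(all(paste(edgeTable(base)$from, edgeTable(base)$to) %in%
                  paste(edgeTable(wider)$from, edgeTable(wider)$to)))
})

test_that("SIF round trip preserves the canonical edge set and node set", {
  s <- generateComplex(synthParams(nResPerChain = 8, nWaters = 12, seed = 4))
  rin <- buildRIN(s, "wet")
  f <- tempfile(fileext = ".sif")
  writeSIF(rin, f)
  back <- readSIF(f)
  expect_equal(back$edges, edgeTable(rin), ignore_attr = TRUE)
  expect_setequal(back$nodes, nodeTable(rin)$label)
})
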