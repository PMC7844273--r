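# Gene-order extraction, comparison, and tree character mapping.

test_that("the canonical vertebrate order has the expected structure", {
  ref <- canon()
  expect_length(ref$labels, 39L)
  i <- which(ref$labels == "-ND6")
  expect_equal(ref$labels[i:(i + 2L)], c("-ND6", "-E", "Cytb"))
  expect_equal(ref$labels[which(ref$labels == "ND5") + 1L], "-ND6")
  for (k in c(1L, 7L, 20L)) {
    expect_true(order_identical(rotate_order(ref, k), ref))
  }
})

test_that("extract_order reads the rearranged suffix off the published table", {
  obs <- extract_order(mcin())
  expect_equal(utils::tail(obs$labels, 7L),
               c("Cytb", "T", "CR1", "-ND6", "-E", "-P", "CR2"))
  expect_equal(obs$labels[1L], "F")
  # tRNA-free "major gene" order
  major <- extract_order(mcin(), include_trna = FALSE)
  expect_length(major$labels, 18L)  # 13 PCG + 2 rRNA + OL + 2 CR
  expect_false(any(c("F", "T", "-E", "-P") %in% major$labels))
})

test_that("a synthesized canonical genome extracts to the canonical order", {
  syn <- synthesize(synthesis_config(tdrl_events = list(), seed = 2))
  expect_true(order_identical(extract_order(syn$annotation), canon()))
})

test_that("an inverted gene extracts with its sign flipped", {
  syn <- synthesize(synthesis_config(tdrl_events = list(), seed = 2))
  f <- syn$annotation$features
  f$strand[f$name == "COI"] <- "L"
  ann2 <- mito_annotation(f, genome_length = syn$annotation$genome_length,
                          quiet = TRUE)
  o <- extract_order(ann2)
  expect_true("-COI" %in% o$labels)
  expect_true(order_identical(o, perturb_order(canon(), "invert", block = "COI")))
})

test_that("comparison of the observed order against the canonical reference", {
  cmp <- compare_orders(extract_order(mcin()), canon())
  expect_setequal(cmp$kind, c("translocation", "duplication"))
  expect_length(cmp$moved_blocks, 1L)
  b <- cmp$moved_blocks[[1L]]
  expect_equal(b$block, c("-ND6", "-E"))
  expect_equal(b$new_context, c("T", "-P"))
  expect_equal(b$old_context, c("ND5", "Cytb"))
  expect_equal(cmp$duplicated, "CR")
  expect_length(cmp$lost, 0L)
  # CR2 sits in the reference CR context, so CR1 is called the duplicate
  dm <- cmp$duplicate_mapping
  expect_true(dm$kept_as_reference[dm$label == "CR2"])
  expect_false(dm$kept_as_reference[dm$label == "CR1"])
})

test_that("an order compares identical to itself under any rotation", {
  ref <- canon()
  for (k in c(0L, 5L, 21L)) {
    cmp <- compare_orders(rotate_order(ref, k), ref)
    expect_equal(cmp$kind, "identical")
    expect_length(cmp$moved_blocks, 0L)
  }
})

test_that("a sign-flipped gene is called an inversion", {
  obs <- perturb_order(canon(), "invert", block = "COI")
  cmp <- compare_orders(obs, canon())
  expect_equal(cmp$kind, "inversion")
  expect_equal(cmp$moved_blocks[[1L]]$block, "-COI")
})

test_that("simulated translocations are recovered as moved blocks", {
  ref <- gene_order(paste0("g", 1:12), circular = TRUE)
  # blocks moved across a segment longer than themselves, so the minimal
  # single-block explanation is unique (a circular order always admits the
  # complementary explanation when the jumped-over segment has equal size)
  cases <- list(
    list(block = c("g5", "g6"), after = "g10"),
    list(block = "g3", after = "g8"),
    list(block = c("g7", "g8", "g9"), after = "g2"),
    list(block = c("g2", "g3"), after = "g7"))
  for (cs in cases) {
    obs <- perturb_order(ref, "translocate", block = cs$block, after = cs$after)
    cmp <- compare_orders(obs, ref)
    expect_true("translocation" %in% cmp$kind || "shuffling" %in% cmp$kind)
    expect_equal(cmp$moved_blocks[[1L]]$block, cs$block)
    expect_equal(cmp$moved_blocks[[1L]]$new_context[1L], cs$after)
  }
})

test_that("comparison is equivariant under label renaming", {
  ref <- gene_order(c("a", "-b", "c", "d", "-e", "f"), circular = TRUE)
  obs <- perturb_order(ref, "translocate", block = c("-b"), after = "e")
  cmp <- compare_orders(obs, ref)
  ren <- c(a = "w1", b = "w2", c = "w3", d = "w4", e = "w5", f = "w6")
  rename <- function(o) {
    u <- sub("^-", "", o$labels)
    gene_order(ifelse(startsWith(o$labels, "-"),
                      paste0("-", ren[u]), ren[u]), circular = TRUE)
  }
  cmp2 <- compare_orders(rename(obs), rename(ref))
  expect_equal(cmp2$kind, cmp$kind)
  expect_equal(sub("^-", "", cmp2$moved_blocks[[1L]]$block),
               unname(ren[sub("^-", "", cmp$moved_blocks[[1L]]$block)]))
})

test_that("comparing disjoint label sets is an error", {
  expect_error(compare_orders(gene_order(c("x", "y")), gene_order(c("p", "q"))),
               "disjoint")
})

test_that("monophyly of a rearrangement character is assessed on a tree", {
  tr <- "((A,B),(C,(D,E)));"
  st <- c(A = "canonical", B = "canonical",
          C = "rearranged", D = "rearranged", E = "rearranged")
  rep <- map_character_on_tree(tr, st)
  expect_true(rep$rearranged$monophyletic)
  expect_equal(sort(rep$rearranged$smallest_clade), c("C", "D", "E"))
  st2 <- st
  st2[c("A", "D")] <- "rearranged"
  st2[c("C", "E")] <- "canonical"
  rep2 <- map_character_on_tree(tr, st2)
  expect_false(rep2$rearranged$monophyletic)
  expect_error(map_character_on_tree(tr, c(st, Z = "rearranged")), "unknown tip")
  expect_error(map_character_on_tree(tr, st[-1L]), "no state")
})

test_that("the five rearranged anguilliform families form a clade on the reference topology", {
  # 15-family topology with the rearranged families grouped at the bottom
  tr <- paste0(
    "(Outgroup,(Anguillidae,(Moringuidae,(Chlopsidae,(Muraenidae,",
    "(Heterenchelyidae,(Myrocongridae,(Nemichthyidae,(Serrivomeridae,",
    "(Synaphobranchidae,((Derichthyidae,Nettastomatidae),(Congridae,",
    "(Muraenesocidae,Ophichthidae)))))))))))));")
  rearranged <- c("Derichthyidae", "Nettastomatidae", "Congridae",
                  "Muraenesocidae", "Ophichthidae")
  tips <- ape::read.tree(text = tr)$tip.label
  st <- stats::setNames(ifelse(tips %in% rearranged, "rearranged", "canonical"),
                        tips)
  rep <- map_character_on_tree(tr, st)
  expect_true(rep$rearranged$monophyletic)
  expect_equal(sort(rep$rearranged$smallest_clade), sort(rearranged))
  expect_false(rep$canonical$monophyletic)  # outgroup splits the canonical tips
})
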