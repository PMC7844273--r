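# TDRL event algebra, scenario inference, and model adjudication.

test_that("applying the six-element duplication-loss event yields the observed order", {
  res <- apply_tdrl(canon(), muraenesox_tdrl_event())
  expect_equal(utils::tail(res$labels, 7L),
               c("Cytb", "T", "CR1", "-ND6", "-E", "-P", "CR2"))
  expect_true(order_identical(res, extract_order(mcin())))
})

test_that("degenerate events behave as defined", {
  ref <- gene_order(c("a", "b", "c", "d"))
  # single-element window kept only in copy 1: order unchanged
  expect_true(order_identical(apply_tdrl(ref, tdrl_event("b", "b", character(0))),
                              ref))
  # everything kept in both copies: full tandem duplication
  full <- apply_tdrl(ref, tdrl_event(c("b", "c"), c("b", "c"), c("b", "c")))
  expect_equal(full$labels, c("a", "b1", "c1", "b2", "c2", "d"))
  # a label kept in neither copy is an incomplete loss
  expect_error(apply_tdrl(ref, tdrl_event(c("b", "c"), "b", character(0))),
               "incomplete loss")
  # strand signs ride along unchanged
  ref2 <- gene_order(c("a", "-b", "c"))
  res2 <- apply_tdrl(ref2, tdrl_event(c("-b", "c"), "c", "b"))
  expect_equal(res2$labels, c("a", "c", "-b"))
})

test_that("the minimal scenario for the observed order is the unique 6-token window", {
  sc <- infer_tdrl(extract_order(mcin()), canon(), max_events = 1L)
  expect_true(sc$feasible)
  expect_equal(sc$n_events, 1L)
  e <- sc$scenarios[[1L]]$events[[1L]]
  expect_equal(e$window, c("-ND6", "-E", "Cytb", "T", "-P", "CR"))
  expect_setequal(e$kept1, c("Cytb", "T", "CR"))
  expect_setequal(e$kept2, c("ND6", "E", "P", "CR"))
  # unique at the minimal window length
  wl <- vapply(sc$scenarios, function(s) length(s$events[[1L]]$window),
               integer(1L))
  expect_equal(sum(wl == 6L), 1L)
  expect_true(order_identical(sc$scenarios[[1L]]$result, extract_order(mcin())))
})

test_that("identical orders need zero events and sign flips are infeasible", {
  ref <- canon()
  sc0 <- infer_tdrl(rotate_order(ref, 4L), ref)
  expect_true(sc0$feasible)
  expect_length(sc0$scenarios[[1L]]$events, 0L)
  # TDRL cannot invert: a sign-flipped block is infeasible at any depth
  inv <- perturb_order(ref, "invert", block = c("COI"))
  sc1 <- infer_tdrl(inv, ref, max_events = 3L)
  expect_false(sc1$feasible)
  expect_match(sc1$note, "strand")
  # and exhaustive search confirms it on a desk-scale order
  small <- gene_order(c("a", "b", "c", "d", "e", "f"))
  sc2 <- infer_tdrl(perturb_order(small, "invert", block = c("b", "c")),
                    small, max_events = 2L)
  expect_false(sc2$feasible)
})

test_that("apply then infer round-trips on random seeded cases", {
  set.seed(101)
  for (i in 1:30) {
    ref <- random_order(sample(6:9, 1L), with_cr = (i %% 2L == 0L))
    ev <- random_event(ref)
    obs <- apply_tdrl(ref, ev)
    sc <- infer_tdrl(obs, ref, max_events = 1L)
    expect_true(sc$feasible, info = paste("case", i))
    expect_true(arrangements_equal(sc$scenarios[[1L]]$result, obs, ref),
                info = paste("case", i))
    # every enumerated scenario reproduces the observed arrangement (up to
    # copy-suffix numbering; a random event can also be an identity, in
    # which case the scenario is empty)
    expect_true(all(vapply(sc$scenarios, function(s)
      arrangements_equal(s$result, obs, ref), logical(1L))),
      info = paste("case", i))
    if (length(sc$scenarios[[1L]]$events) > 0L) {
      # and the applied window appears among the explanations
      wins <- vapply(sc$scenarios, function(s)
        paste(s$events[[1L]]$window, collapse = ","), character(1L))
      expect_true(paste(ev$window, collapse = ",") %in% wins ||
                    order_identical(sc$scenarios[[1L]]$result, obs),
                  info = paste("case", i))
    }
  }
})

test_that("the interleaving criterion agrees with brute-force bipartition enumeration", {
  set.seed(55)
  for (rep in 1:4) {
    ref <- random_order(7L, with_cr = TRUE)
    # half the cases are genuine TDRL products, half are random shuffles
    obs <- if (rep %% 2L == 0L) {
      apply_tdrl(ref, random_event(ref))
    } else {
      gene_order(sample(ref$labels), circular = TRUE)
    }
    brute <- brute_force_one_event(obs, ref, max_len = 6L)
    brute_windows <- unique(vapply(brute, function(h)
      paste(h$window, collapse = ","), character(1L)))
    for (p in 1:length(ref$labels)) {
      for (L in 2:6) {
        idx <- ((p - 1L) + 0:(L - 1L)) %% length(ref$labels) + 1L
        W <- ref$labels[idx]
        expect_equal(tdrl_window_feasible(obs, ref, W),
                     paste(W, collapse = ",") %in% brute_windows,
                     info = paste(rep, paste(W, collapse = ",")))
      }
    }
  }
})

test_that("inference is invariant under rotation of both orders", {
  obs <- extract_order(mcin())
  ref <- canon()
  sc <- infer_tdrl(obs, ref, max_events = 1L)
  sc_rot <- infer_tdrl(rotate_order(obs, 13L), rotate_order(ref, 7L),
                       max_events = 1L)
  key <- function(s) {
    e <- s$events[[1L]]
    paste(paste(e$window, collapse = ","), paste(e$kept1, collapse = ","),
          paste(e$kept2, collapse = ","), sep = "|")
  }
  expect_equal(vapply(sc$scenarios, key, character(1L)),
               vapply(sc_rot$scenarios, key, character(1L)))
})

test_that("two-event transformations are found by the deeper search", {
  ref <- gene_order(c("a", "b", "c", "d", "e", "f"))
  step1 <- apply_tdrl(ref, tdrl_event(c("b", "c", "d"), "d", c("b", "c")))
  obs <- apply_tdrl(step1, tdrl_event(c("b", "c", "e"), c("c", "e"), "b"))
  expect_false(infer_tdrl(obs, ref, max_events = 1L)$feasible)
  sc <- infer_tdrl(obs, ref, max_events = 2L)
  expect_true(sc$feasible)
  expect_equal(sc$n_events, 2L)
  expect_true(order_identical(sc$scenarios[[1L]]$result, obs))
})

test_that("model adjudication matches the published analysis", {
  ann <- mcin()
  ad <- adjudicate_models(extract_order(ann), canon(),
                          spacers = intergenic_spacers(ann))
  expect_true(ad$tdrl$plausible)
  expect_false(ad$recombination$plausible)
  expect_false(ad$tdnl$plausible)
  expect_false(ad$drrl$plausible)
  expect_equal(ad$verdict, "tdrl")
  # the four duplication-remnant spacers in the rearranged region
  expect_equal(sort(ad$details$supporting_spacers$gap), c(1L, 4L, 23L, 35L))
})

test_that("adjudication on controls: identical, inversion, polarity-split, CR-driven", {
  ref <- canon()
  # identical orders: nothing to explain
  ad0 <- adjudicate_models(ref, ref)
  expect_false(any(ad0$recombination$plausible, ad0$tdrl$plausible,
                   ad0$tdnl$plausible, ad0$drrl$plausible))
  expect_match(ad0$verdict, "none fits")
  # inversion-only: recombination in, TDRL out
  ad1 <- adjudicate_models(perturb_order(ref, "invert", block = "COI"), ref)
  expect_true(ad1$recombination$plausible)
  expect_false(ad1$tdrl$plausible)
  expect_false(ad1$tdnl$plausible)
  # polarity-split translocation without CR duplication (M. bagio-like):
  # TDNL-compatible, DRRL not (single CR)
  bagio <- perturb_order(ref, "translocate", block = c("-ND6", "-E"),
                         after = "T")
  ad2 <- adjudicate_models(bagio, ref)
  expect_true(ad2$tdnl$plausible)
  expect_true(ad2$tdrl$plausible)
  expect_false(ad2$drrl$plausible)
  # two CRs delimiting a polarity-partitioned window copy: DRRL-compatible
  r2 <- gene_order(c("X", "-a", "c", "-b", "d", "CR", "Y"))
  o2 <- gene_order(c("X", "CR1", "c", "d", "-a", "-b", "CR2", "Y"))
  ad3 <- adjudicate_models(o2, r2)
  expect_true(ad3$drrl$plausible)
  expect_false(ad3$tdnl$plausible)
})

test_that("scenarios serialize to JSON", {
  sc <- infer_tdrl(extract_order(mcin()), canon(), max_events = 1L)
  js <- jsonlite::fromJSON(scenarios_json(sc), simplifyVector = FALSE)
  expect_true(js$feasible)
  expect_equal(js$n_events, 1L)
  ev <- js$scenarios[[1L]]$events[[1L]]
  expect_equal(unlist(ev$window), c("-ND6", "-E", "Cytb", "T", "-P", "CR"))
})
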