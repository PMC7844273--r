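# Tandem duplication-random loss (TDRL) scenario inference and
# rearrangement-model adjudication (recombination / TDRL / TDNL / DRRL).

#' Construct a TDRL event
#'
#' A TDRL event duplicates a contiguous window of the reference order in
#' tandem and then loses duplicates: each window element is kept in the
#' first copy, the second copy, or both (retained duplicates, e.g. a
#' control region). The resulting order is
#' `prefix + copy1-kept (in window order) + copy2-kept (in window order) +
#' suffix`. An element kept in neither copy would be a deletion and is
#' disallowed.
#'
#' @param window Character vector of signed reference tokens, contiguous in
#'   the reference the event is applied to.
#' @param kept1,kept2 Unsigned label sets kept in the first and second copy.
#' @return An object of class `tdrl_event`.
#' @examples
#' tdrl_event(c("-ND6", "-E", "Cytb", "T", "-P", "CR"),
#'            kept1 = c("Cytb", "T", "CR"), kept2 = c("ND6", "E", "P", "CR"))
#' @export
tdrl_event <- function(window, kept1, kept2) {
  window <- as.character(window)
  win_u <- tok_label(window)
  if (anyDuplicated(win_u)) stop("window labels must be unique")
  kept1 <- as.character(kept1); kept2 <- as.character(kept2)
  if (!all(kept1 %in% win_u) || !all(kept2 %in% win_u)) {
    stop("kept sets must be subsets of the window labels")
  }
  structure(list(window = window, kept1 = kept1, kept2 = kept2),
            class = "tdrl_event")
}

#' @export
print.tdrl_event <- function(x, ...) {
  cat(sprintf("TDRL event: duplicate (%s); copy1 keeps {%s}, copy2 keeps {%s}\n",
              paste(x$window, collapse = ","),
              paste(x$kept1, collapse = ","),
              paste(x$kept2, collapse = ",")))
  invisible(x)
}

#' The TDRL event explaining the Muraenesox cinereus gene order
#'
#' Duplication of the six-element window ND6-trnE-Cytb-trnT-trnP-CR of the
#' canonical vertebrate order, with the first copy keeping Cytb, trnT and
#' CR and the second copy keeping ND6, trnE, trnP and CR (the control
#' region retained in both copies).
#'
#' @return A [tdrl_event].
#' @export
muraenesox_tdrl_event <- function() {
  tdrl_event(c("-ND6", "-E", "Cytb", "T", "-P", "CR"),
             kept1 = c("Cytb", "T", "CR"),
             kept2 = c("ND6", "E", "P", "CR"))
}

#' Apply a TDRL event to a gene order
#'
#' @param ref A `gene_order` containing the event's window as a contiguous
#'   (circularly, if `ref` is circular) run of tokens.
#' @param e A [tdrl_event]; every window label must be kept in at least one
#'   copy.
#' @return The resulting `gene_order`. Labels kept in both copies appear
#'   twice, suffixed `1` (first copy) and `2` (second copy).
#' @export
apply_tdrl <- function(ref, e) {
  stopifnot(inherits(ref, "gene_order"), inherits(e, "tdrl_event"))
  win <- e$window
  win_u <- tok_label(win)
  missing_lab <- setdiff(win_u, union(e$kept1, e$kept2))
  if (length(missing_lab) > 0L) {
    stop("window label(s) kept in neither copy (incomplete loss): ",
         paste(missing_lab, collapse = ", "))
  }
  lab <- ref$labels
  n <- length(lab)
  L <- length(win)
  if (L > n) stop("window longer than the order")
  p <- NA_integer_
  k_used <- 0L
  for (k in 0:(if (ref$circular) n - 1L else 0L)) {
    rot <- rotate_vec(lab, k)
    hit <- which(vapply(seq_len(n - L + 1L), function(i) {
      identical(rot[i:(i + L - 1L)], win)
    }, logical(1L)))
    if (length(hit) > 0L) { p <- hit[1L]; k_used <- k; break }
  }
  if (is.na(p)) stop("window not found as a contiguous run in the order")
  rot <- rotate_vec(lab, k_used)
  both <- intersect(e$kept1, e$kept2)
  copy_tokens <- function(kept, suffix) {
    keep <- win[win_u %in% kept]
    keep_u <- tok_label(keep)
    ifelse(keep_u %in% both,
           make_tok(paste0(keep_u, suffix), tok_strand(keep)),
           keep)
  }
  res <- c(if (p > 1L) rot[1:(p - 1L)],
           copy_tokens(e$kept1, "1"),
           copy_tokens(e$kept2, "2"),
           if (p + L <= n) rot[(p + L):n])
  gene_order(res, circular = ref$circular)
}

## --- single-event search ----------------------------------------------

## Map observed tokens onto the reference label space (strip copy suffixes
## like CR1 -> CR when the base exists in the reference) keeping signs.
obs_in_ref_space <- function(obs, ref) {
  ref_u <- tok_label(ref$labels)
  u <- tok_label(obs$labels)
  make_tok(base_label(u, ref_u), tok_strand(obs$labels))
}

## All single TDRL events turning ref into obs. Returns a list of
## tdrl_event objects (deduplicated).
one_event_candidates <- function(obs_s, ref_l, circular, max_window,
                                 allowed_dup) {
  n <- length(ref_l)
  d <- length(obs_s) - n
  found <- new.env(parent = emptyenv())
  rotations <- if (circular) 0:(n - 1L) else 0L
  for (r in rotations) {
    refR <- rotate_vec(ref_l, r)
    anchors <- which(obs_s == refR[1L])
    for (a in anchors) {
      obsR <- rotate_vec(obs_s, a - 1L)
      m <- length(obsR)
      # longest common prefix and suffix between refR and obsR
      lcp <- 0L
      while (lcp < n && refR[lcp + 1L] == obsR[lcp + 1L]) lcp <- lcp + 1L
      lcs <- 0L
      while (lcs < n && refR[n - lcs] == obsR[m - lcs]) lcs <- lcs + 1L
      for (p in 2:n) {
        if (p - 1L > lcp) break
        max_L <- min(max_window, n - p + 1L)
        for (L in seq_len(max_L)) {
          sfx <- n - (p + L - 1L)
          if (sfx > lcs) next
          W <- refR[p:(p + L - 1L)]
          W_u <- tok_label(W)
          M <- obsR[p:(p + L + d - 1L)]
          M_u <- tok_label(M)
          dup_here <- M_u[duplicated(M_u)]
          if (length(dup_here) != d) next
          if (!identical(csort(M_u), csort(c(W_u, dup_here)))) next
          if (!all(dup_here %in% allowed_dup)) next
          win_idx <- stats::setNames(seq_along(W_u), W_u)
          for (k in 0:length(M)) {
            left <- M[seq_len(k)]
            right <- if (k < length(M)) M[(k + 1L):length(M)] else character(0)
            if (valid_copy(left, W, win_idx) && valid_copy(right, W, win_idx)) {
              left_u <- tok_label(left); right_u <- tok_label(right)
              if (!setequal(union(left_u, right_u), W_u)) next
              if (!setequal(intersect(left_u, right_u), dup_here)) next
              key <- paste(paste(W, collapse = ","),
                           paste(left_u, collapse = ","),
                           paste(right_u, collapse = ","), sep = "|")
              if (is.null(found[[key]])) {
                found[[key]] <- tdrl_event(W, left_u, right_u)
              }
            }
          }
        }
      }
    }
  }
  evs <- as.list(found)
  evs[order(vapply(evs, function(e) length(e$window), integer(1L)),
            vapply(evs, function(e) paste(e$window, collapse = ","), character(1L)),
            vapply(evs, function(e) paste(e$kept1, collapse = ","), character(1L)),
            method = "radix")]
}

## a copy is valid if its labels are unique, appear in window order, and
## carry the window's strand signs
valid_copy <- function(part, W, win_idx) {
  if (length(part) == 0L) return(TRUE)
  u <- tok_label(part)
  if (anyDuplicated(u)) return(FALSE)
  idx <- win_idx[u]
  if (anyNA(idx)) return(FALSE)
  if (is.unsorted(idx, strictly = TRUE)) return(FALSE)
  all(part == W[idx])
}

#' One-event TDRL feasibility of a given window (interleaving criterion)
#'
#' A single TDRL event over `window` can produce `obs` from `ref` iff,
#' outside the window image, `obs` equals `ref`, and the observed tokens of
#' the window split into two subsequences (copy 1 then copy 2) each
#' respecting window order. This is the fast feasibility check that the
#' exhaustive loss-bipartition enumeration must agree with.
#'
#' @param obs,ref `gene_order` objects.
#' @param window Character vector of signed tokens, contiguous in `ref`.
#' @param allowed_dup Labels allowed to be retained in both copies
#'   (default: CR-class tokens).
#' @return `TRUE` or `FALSE`.
#' @export
tdrl_window_feasible <- function(obs, ref, window,
                                 allowed_dup = cr_labels(ref)) {
  obs_s <- obs_in_ref_space(obs, ref)
  evs <- one_event_candidates(obs_s, ref$labels, obs$circular && ref$circular,
                              max_window = length(window), allowed_dup = allowed_dup)
  any(vapply(evs, function(e) identical(e$window, as.character(window)),
             logical(1L)))
}

cr_labels <- function(x) {
  labs <- tok_label(if (inherits(x, "gene_order")) x$labels else x)
  unique(labs[token_class(labs) == "CR"])
}

#' Infer TDRL scenarios transforming one gene order into another
#'
#' Exhaustive search for minimal sequences of TDRL events turning `ref`
#' into `obs`. Single events are found by scanning every contiguous window
#' (up to `max_window` tokens, all rotations when circular) and every
#' loss bipartition consistent with the observed order; retention in both
#' copies is allowed only for control-region-class labels by default
#' (`both_kept` to relax). Because a TDRL event never flips strand, any
#' strand-sign mismatch between `obs` and `ref` is immediately infeasible.
#' Multi-event search (up to `max_events`, at most 3) enumerates first
#' events generatively and is exhaustive only for desk-scale orders
#' (<= 12 tokens); larger inputs report an incomplete search rather than
#' claiming infeasibility.
#'
#' @param obs,ref `gene_order` objects; `obs` labels must be `ref` labels
#'   up to duplications.
#' @param max_events Maximum number of events to consider (<= 3).
#' @param max_window Maximum window length (default 12).
#' @param both_kept Labels allowed in both copies; default CR-class labels.
#' @return An object of class `tdrl_scenarios`: list with `scenarios`
#'   (each a list of [tdrl_event]s plus the resulting order), `feasible`,
#'   `n_events`, `search_complete` and a `note`. Scenarios are sorted by
#'   (number of events, total window length, window, kept1).
#' @export
infer_tdrl <- function(obs, ref, max_events = 1L, max_window = 12L,
                       both_kept = NULL) {
  stopifnot(inherits(obs, "gene_order"), inherits(ref, "gene_order"))
  if (max_events > 3L) stop("max_events must be <= 3")
  circular <- obs$circular && ref$circular
  ref_l <- ref$labels
  ref_u <- tok_label(ref_l)
  obs_s <- obs_in_ref_space(obs, ref)
  obs_u <- tok_label(obs_s)
  if (is.null(both_kept)) both_kept <- cr_labels(ref)

  extra <- setdiff(obs_u, ref_u)
  if (length(extra) > 0L) {
    stop("observed labels not reachable from reference: ",
         paste(unique(extra), collapse = ", "))
  }

  result <- function(scenarios, complete = TRUE, note = "") {
    scenarios <- sort_scenarios(scenarios)
    structure(list(scenarios = scenarios,
                   feasible = length(scenarios) > 0L,
                   n_events = if (length(scenarios) > 0L)
                     length(scenarios[[1L]]$events) else NA_integer_,
                   search_complete = complete, note = note,
                   obs = obs, ref = ref),
              class = "tdrl_scenarios")
  }

  # losses are not part of this event model
  if (length(obs_s) < length(ref_l)) {
    return(result(list(), note = "observed order has fewer elements than the reference; loss-only differences are outside the TDRL event model"))
  }
  # sign preservation: TDRL cannot invert
  sign_tab_obs <- unique(data.frame(u = obs_u, s = tok_strand(obs_s)))
  sign_tab_ref <- unique(data.frame(u = ref_u, s = tok_strand(ref_l)))
  merged <- merge(sign_tab_obs, sign_tab_ref, by = "u")
  if (any(merged$s.x != merged$s.y)) {
    return(result(list(), note = "strand signs differ between the orders; TDRL events preserve strand, so no scenario exists at any depth"))
  }
  dup_needed <- unique(obs_u[duplicated(obs_u)])
  if (!all(dup_needed %in% both_kept)) {
    return(result(list(), note = paste0(
      "duplicated label(s) ", paste(setdiff(dup_needed, both_kept), collapse = ","),
      " are not in the both-copies retention class")))
  }

  if (length(obs_s) == length(ref_l) && eq_circular(obs_s, ref_l, circular)) {
    return(result(list(list(events = list(), result = obs))))
  }

  evs <- one_event_candidates(obs_s, ref_l, circular, max_window, both_kept)
  if (length(evs) > 0L) {
    scens <- lapply(evs, function(e) {
      list(events = list(e), result = apply_tdrl(ref, e))
    })
    return(result(scens))
  }
  if (max_events < 2L) {
    return(result(list(), note = "no single-event scenario"))
  }
  if (length(ref_l) > 12L) {
    return(result(list(), complete = FALSE,
                  note = "no single-event scenario; exhaustive multi-event search is only attempted for orders of <= 12 tokens"))
  }
  # depth >= 2: enumerate first events generatively, last level guided
  scens <- multi_event_search(obs, ref, obs_s, max_events, max_window,
                              both_kept, circular)
  result(scens, note = if (length(scens) == 0L)
    sprintf("no scenario within %d events", max_events) else "")
}

sort_scenarios <- function(scens) {
  if (length(scens) == 0L) return(scens)
  ne <- vapply(scens, function(s) length(s$events), integer(1L))
  wl <- vapply(scens, function(s)
    sum(vapply(s$events, function(e) length(e$window), integer(1L))), integer(1L))
  w1 <- vapply(scens, function(s)
    if (length(s$events) > 0L) paste(s$events[[1L]]$window, collapse = ",") else "",
    character(1L))
  k1 <- vapply(scens, function(s)
    if (length(s$events) > 0L) paste(s$events[[1L]]$kept1, collapse = ",") else "",
    character(1L))
  scens[order(ne, wl, w1, k1, method = "radix")]
}

## generative enumeration of single pure-bipartition events (no label kept
## in both copies) on an order; used for the non-final levels of the
## multi-event search, so intermediate orders stay duplicate-free
all_bipartition_events <- function(ord, max_window) {
  lab <- ord$labels
  n <- length(lab)
  evs <- list()
  for (p in 1:n) {
    for (L in 2:min(max_window, n - 1L)) {
      idx <- ((p - 1L) + 0:(L - 1L)) %% n + 1L
      if (!ord$circular && any(diff(idx) != 1L)) next
      W <- lab[idx]
      W_u <- tok_label(W)
      if (anyDuplicated(W_u)) next
      for (mask in 1:(2^L - 2L)) {
        bits <- bitwAnd(mask, 2^(0:(L - 1L))) > 0L
        evs[[length(evs) + 1L]] <- tdrl_event(W, W_u[bits], W_u[!bits])
      }
    }
  }
  evs
}

## iterative-deepening multi-event search: the first (max - 1) events are
## pure bipartitions enumerated generatively; the final event (which may
## retain a control region in both copies) is found by the guided
## single-event scan against obs
multi_event_search <- function(obs, ref, obs_s, max_events, max_window,
                               both_kept, circular) {
  frontier <- list(list(order = ref, events = list()))
  for (total in 2:max_events) {
    new_frontier <- list()
    scens <- list()
    for (state in frontier) {
      evs <- all_bipartition_events(state$order, max_window)
      for (e in evs) {
        res <- apply_tdrl(state$order, e)
        if (eq_circular(res$labels, state$order$labels, circular)) next
        st <- list(order = res, events = c(state$events, list(e)))
        fin <- one_event_candidates(obs_s, res$labels, circular, max_window,
                                    both_kept)
        for (fe in fin) {
          scens[[length(scens) + 1L]] <-
            list(events = c(st$events, list(fe)),
                 result = apply_tdrl(res, fe))
        }
        new_frontier[[length(new_frontier) + 1L]] <- st
      }
    }
    if (length(scens) > 0L) return(scens)
    frontier <- new_frontier
  }
  list()
}

#' @export
print.tdrl_scenarios <- function(x, ...) {
  if (!x$feasible) {
    cat("No TDRL scenario found.",
        if (nzchar(x$note)) paste0(" (", x$note, ")"), "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("%d minimal TDRL scenario(s) with %d event(s):\n",
              length(x$scenarios), x$n_events))
  for (i in seq_along(x$scenarios)) {
    s <- x$scenarios[[i]]
    cat(sprintf(" scenario %d:\n", i))
    for (e in s$events) {
      cat("   "); print(e)
    }
  }
  invisible(x)
}

#' Serialize TDRL scenarios to JSON
#'
#' @param x A `tdrl_scenarios` object.
#' @return A JSON string (events with window labels, kept sets, and the
#'   resulting order).
#' @export
scenarios_json <- function(x) {
  stopifnot(inherits(x, "tdrl_scenarios"))
  payload <- list(
    feasible = x$feasible,
    n_events = x$n_events,
    note = x$note,
    scenarios = lapply(x$scenarios, function(s) list(
      events = lapply(s$events, function(e) list(
        window = e$window, kept_in_copy1 = e$kept1, kept_in_copy2 = e$kept2)),
      result = s$result$labels))
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE)
}

## --- model adjudication -------------------------------------------------

## minimal circular span of obs indices covering all positions in `pos`
span_indices <- function(pos, n) {
  pos <- sort(unique(pos))
  k <- length(pos)
  if (k == 0L) return(integer(0))
  if (k == 1L) return(pos)
  gaps <- c(diff(pos), pos[1L] + n - pos[k])
  g <- which.max(gaps)
  start <- pos[(g %% k) + 1L]
  end <- pos[g]
  if (start <= end) start:end else c(start:n, 1:end)
}

#' Adjudicate rearrangement models for an observed gene order
#'
#' Applies rule-based plausibility checks for the four mechanisms commonly
#' invoked for mitochondrial gene rearrangement:
#'
#' * recombination: plausible iff an inverted block exists (recombination
#'   exchanges and reverses fragments; nothing else here inverts);
#' * TDRL (tandem duplication-random loss): plausible iff a TDRL scenario
#'   exists and, when a spacer report is supplied, at least 2 positive
#'   intergenic spacers fall inside or immediately flank the duplicated
#'   window's image in the observed order (spacers as duplication
#'   remnants);
#' * TDNL (tandem duplication-non-random loss): plausible iff a
#'   single-event scenario exists in which loss is fully determined by
#'   transcriptional polarity - the two copies keep exactly the window's
#'   heavy- and light-strand elements respectively, and no element is
#'   retained in both copies;
#' * DRRL (double replication-random loss): plausible iff the observed
#'   order carries two control regions and the elements strictly between
#'   them are a polarity-partitioned copy of a contiguous reference window
#'   containing the control region.
#'
#' @param obs,ref `gene_order` objects.
#' @param spacers Optional `spacer_report` computed from the annotation
#'   that produced `obs` (same feature order).
#' @param max_events Passed to [infer_tdrl()].
#' @return An object of class `model_adjudication`: per model a
#'   `plausible` flag and a one-line `reason`, plus a `verdict` (the
#'   plausible models, or `"none fits"`) and supporting `details`.
#' @export
adjudicate_models <- function(obs, ref, spacers = NULL, max_events = 2L) {
  cmp <- compare_orders(obs, ref)
  v <- function(flag, reason) list(plausible = flag, reason = reason)

  if (identical(cmp$kind, "identical")) {
    out <- list(
      recombination = v(FALSE, "no rearrangement"),
      tdrl = v(FALSE, "no rearrangement"),
      tdnl = v(FALSE, "no rearrangement"),
      drrl = v(FALSE, "no rearrangement"),
      verdict = "none fits (orders are identical; no rearrangement to explain)",
      details = list(call = cmp))
    class(out) <- "model_adjudication"
    return(out)
  }

  inv <- any(vapply(cmp$moved_blocks, function(b) b$type == "inversion",
                    logical(1L)))
  recomb <- if (inv) {
    v(TRUE, "an inverted block exists; recombination is the only considered mechanism that reverses fragments")
  } else {
    v(FALSE, "no inverted block; recombination predicts exchange/reversal of small fragments")
  }

  scen <- infer_tdrl(obs, ref, max_events = max_events)
  obs_s <- obs_in_ref_space(obs, ref)
  obs_u <- tok_label(obs_s)
  n <- length(obs_s)

  image_idx <- integer(0)
  support <- NULL
  if (scen$feasible && length(scen$scenarios[[1L]]$events) > 0L) {
    W_u <- tok_label(scen$scenarios[[1L]]$events[[1L]]$window)
    image_idx <- span_indices(which(obs_u %in% W_u), n)
  }

  if (!scen$feasible) {
    tdrl <- v(FALSE, paste0("no TDRL scenario: ", scen$note))
  } else if (is.null(spacers)) {
    tdrl <- v(TRUE, sprintf(
      "a %d-event TDRL scenario exists (spacer evidence not assessed)",
      length(scen$scenarios[[1L]]$events)))
  } else {
    image_set <- tok_label(obs$labels)[image_idx]
    pr <- spacers$pairs
    up_tok <- name_to_token(pr$upstream)
    down_tok <- name_to_token(pr$downstream)
    in_image <- up_tok %in% image_set | down_tok %in% image_set
    support <- pr[in_image & pr$gap > 0L, , drop = FALSE]
    ok <- nrow(support) >= 2L
    tdrl <- v(ok, sprintf(
      "TDRL scenario exists; %d positive spacer(s) inside or flanking the duplicated region%s",
      nrow(support), if (ok) " (duplication remnants)" else " - fewer than the 2 required"))
  }

  # TDNL: a single event whose loss pattern is exactly the polarity split
  tdnl <- v(FALSE, "no single polarity-determined duplication-loss event reproduces the order")
  if (scen$feasible && scen$n_events == 1L) {
    hit <- FALSE
    retained <- FALSE
    for (s in scen$scenarios) {
      e <- s$events[[1L]]
      if (length(intersect(e$kept1, e$kept2)) > 0L) { retained <- TRUE; next }
      W <- e$window
      h_lab <- tok_label(W)[tok_strand(W) == "H"]
      l_lab <- tok_label(W)[tok_strand(W) == "L"]
      if ((setequal(e$kept1, h_lab) && setequal(e$kept2, l_lab)) ||
          (setequal(e$kept1, l_lab) && setequal(e$kept2, h_lab))) {
        hit <- TRUE
        break
      }
    }
    if (hit) {
      tdnl <- v(TRUE, "a single duplication with loss fully determined by strand polarity reproduces the order")
    } else if (retained) {
      tdnl <- v(FALSE, "every explanatory duplication retains an element (the control region) in both copies and interleaves strand polarities; polarity-determined loss would resolve all duplicates into one heavy- and one light-strand block")
    }
  }

  # DRRL: elements between two CRs are a polarity partition of a
  # contiguous reference window containing the CR
  cr_pos <- which(token_class(obs_u) == "CR")
  if (length(cr_pos) < 2L) {
    drrl <- v(FALSE, "fewer than two control regions; DRRL requires duplicated CRs driving double replication")
  } else {
    ref_l <- ref$labels
    ref_cr <- which(token_class(tok_label(ref_l)) == "CR")[1L]
    found <- FALSE
    p1 <- cr_pos[1L]; p2 <- cr_pos[2L]
    arcs <- list(
      if (p2 - p1 > 1L) obs_s[(p1 + 1L):(p2 - 1L)] else NULL,
      {
        rest <- c(if (p2 < n) (p2 + 1L):n, if (p1 > 1L) 1:(p1 - 1L))
        if (length(rest) > 0L) obs_s[rest] else NULL
      })
    m <- length(ref_l)
    if (!is.na(ref_cr)) {
      for (I in arcs) {
        if (is.null(I) || found) next
        for (L in 2:min(length(I) + 1L, m - 1L)) {
          for (off in 0:(L - 1L)) {
            idx <- ((ref_cr - 1L - off) + 0:(L - 1L)) %% m + 1L
            W <- ref_l[idx]
            non_cr <- W[token_class(tok_label(W)) != "CR"]
            h <- non_cr[tok_strand(non_cr) == "H"]
            l <- non_cr[tok_strand(non_cr) == "L"]
            if (identical(I, c(h, l)) || identical(I, c(l, h))) {
              found <- TRUE
              break
            }
          }
          if (found) break
        }
      }
    }
    drrl <- if (found) {
      v(TRUE, "the elements between the two control regions are a polarity-partitioned copy of a contiguous reference window")
    } else {
      v(FALSE, "the elements between the two control regions are not a polarity-partitioned copy of any contiguous reference window (part of the rearranged block lies outside the CR-CR span)")
    }
  }

  models <- list(recombination = recomb, tdrl = tdrl, tdnl = tdnl, drrl = drrl)
  plaus <- names(models)[vapply(models, `[[`, logical(1L), "plausible")]
  out <- c(models, list(
    verdict = if (length(plaus) > 0L) paste(plaus, collapse = ", ") else "none fits",
    details = list(call = cmp, scenarios = scen, image_indices = image_idx,
                   supporting_spacers = support)))
  class(out) <- "model_adjudication"
  out
}

#' @export
print.model_adjudication <- function(x, ...) {
  cat("Rearrangement model adjudication\n")
  for (m in c("recombination", "tdrl", "tdnl", "drrl")) {
    cat(sprintf("  %-13s %-5s %s\n", toupper(m),
                if (x[[m]]$plausible) "yes" else "no", x[[m]]$reason))
  }
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}
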