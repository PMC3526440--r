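# Synthetic phylogeny-aligned data. Sequences evolve from a root along the
# tree under an HKY-like substitution process plus geometric-length
# insertions and deletions; homology is tracked through real-valued column
# keys so the true multiple alignment (ancestors included) is emitted
# without running an aligner. Optional count-level selection maintains a
# minimum number of predicted binding sites inside a target window while
# permitting turnover of the sites themselves.

#' Parameters of the neutral sequence-evolution model
#'
#' Substitutions follow an HKY-style process (transition/transversion ratio
#' `titv`, stationary base composition `base_comp`) with the rate matrix
#' scaled to one expected substitution per site per unit branch length times
#' `subst_rate`. Insertions and deletions occur at `indel_rate` times the
#' substitution rate each, with geometric lengths of mean `indel_mean_len`.
#'
#' @param subst_rate Expected substitutions per site per unit branch length.
#' @param titv Transition/transversion rate ratio (kappa).
#' @param indel_rate Insertion (and, separately, deletion) events per site
#'   per unit branch length, as a fraction of `subst_rate`.
#' @param indel_mean_len Mean indel length (geometric).
#' @param base_comp Stationary base composition (A, C, G, T).
#' @return An `evolution_params` list.
#' @export
sim_params <- function(subst_rate = 1, titv = 2, indel_rate = 0.1,
                       indel_mean_len = 2, base_comp = rep(0.25, 4)) {
  stopifnot(subst_rate >= 0, titv > 0, indel_rate >= 0, indel_mean_len >= 1)
  base_comp <- background(base_comp)
  structure(list(subst_rate = subst_rate, titv = titv,
                 indel_rate = indel_rate, indel_mean_len = indel_mean_len,
                 base_comp = base_comp),
            class = "evolution_params")
}

# HKY rate matrix (rows = from, cols = to), scaled to 1 expected
# substitution per site per unit time at stationarity.
hky_rate_matrix <- function(titv, base_comp) {
  Q <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  is_transition <- function(i, j) (i + j) %in% c(4L, 6L) # A<->G (1,3), C<->T (2,4)
  for (i in 1:4) for (j in 1:4) {
    if (i != j) Q[i, j] <- base_comp[j] * if (is_transition(i, j)) titv else 1
  }
  diag(Q) <- -rowSums(Q)
  rate <- -sum(base_comp * diag(Q))
  Q / rate
}

# Transition probability matrix P(t) = exp(Qt) via eigendecomposition.
hky_transition_matrix <- function(t, params) {
  Q <- hky_rate_matrix(params$titv, params$base_comp)
  e <- eigen(Q)
  P <- e$vectors %*% diag(exp(e$values * t * params$subst_rate)) %*% solve(e$vectors)
  P <- pmax(Re(P), 0)
  P / rowSums(P)
  }

#' Specification of count-level selection on a window
#'
#' Selection acts on the number of predicted binding sites inside a target
#' window of the root sequence (tracked through indels): proposed mutations
#' that would drop the count below `k` are rejected and redrawn. With
#' `turnover = TRUE` (the default) any individual site may be destroyed as
#' long as `k` sites remain, so site positions are free to move; with
#' `turnover = FALSE` every proposal that lowers the count at all is
#' rejected, freezing the sites in place.
#'
#' @param start,end 0-based half-open interval on the root sequence.
#' @param pwm Calibrated [pwm()] defining the predictor under selection.
#' @param k Minimum maintained site count (>= 1).
#' @param turnover Allow site turnover (see Details).
#' @return A `selection_spec` list.
#' @export
selection_spec <- function(start, end, pwm, k = 2L, turnover = TRUE) {
  stopifnot(end > start, k >= 1L, inherits(pwm, "pwm"))
  if (is.na(pwm$threshold)) stop("selection PWM must be calibrated")
  structure(list(start = as.integer(start), end = as.integer(end),
                 pwm = pwm, k = as.integer(k), turnover = isTRUE(turnover)),
            class = "selection_spec")
}

# Internal per-branch mutation. `state` is list(chars, keys); `sel` a list
# of lists(key_lo, key_hi, pwm, k, turnover) in key space.
mutate_branch <- function(state, t, params, sel = list()) {
  chars <- state$chars
  keys <- state$keys
  P <- hky_transition_matrix(t, params)
  comp <- params$base_comp

  in_sel <- function(keys) {
    if (length(sel) == 0L) return(rep(FALSE, length(keys)))
    Reduce(`|`, lapply(sel, function(s) keys >= s$key_lo & keys <= s$key_hi))
  }
  window_count <- function(chars, keys, s) {
    idx <- keys >= s$key_lo & keys <= s$key_hi
    if (!any(idx)) return(0L)
    count_sites_core(match(chars[idx], DNA_BASES), s$lm, s$lm_rc, s$threshold)
  }
  # Does applying `apply_fun` keep every selected window acceptable?
  acceptable <- function(chars2, keys2, before_counts) {
    for (i in seq_along(sel)) {
      cnt <- window_count(chars2, keys2, sel[[i]])
      if (cnt < sel[[i]]$k) return(FALSE)
      if (!sel[[i]]$turnover && cnt < before_counts[i]) return(FALSE)
    }
    TRUE
  }

  # --- substitutions -------------------------------------------------------
  code <- match(chars, DNA_BASES)
  prop <- code
  for (bidx in 1:4) {
    i <- which(code == bidx)
    if (length(i)) prop[i] <- sample.int(4L, length(i), replace = TRUE,
                                         prob = P[bidx, ])
  }
  changed <- which(prop != code)
  sel_mask <- in_sel(keys)
  free <- changed[!sel_mask[changed]]
  chars[free] <- DNA_BASES[prop[free]]
  guarded <- changed[sel_mask[changed]]
  for (i in guarded) {
    before <- vapply(sel, function(s) window_count(chars, keys, s), integer(1))
    ok <- FALSE
    site <- i; newb <- DNA_BASES[prop[i]]
    for (try in 1:20) {
      cand <- chars; cand[site] <- newb
      if (acceptable(cand, keys, before)) { chars <- cand; ok <- TRUE; break }
      # redraw the proposal inside the same window
      s <- sel[[which(vapply(sel, function(s) keys[i] >= s$key_lo &&
                               keys[i] <= s$key_hi, logical(1)))[1L]]]
      win_idx <- which(keys >= s$key_lo & keys <= s$key_hi)
      site <- sample(win_idx, 1L)
      newb <- sample(DNA_BASES, 1L, prob = comp)
    }
  }

  # --- insertions ----------------------------------------------------------
  lam_ind <- params$indel_rate * params$subst_rate * t
  n_ins <- stats::rpois(1L, lam_ind * (length(chars) + 1L))
  for (e in seq_len(n_ins)) {
    pos <- sample.int(length(chars) + 1L, 1L) # insert before position pos
    len <- 1L + stats::rgeom(1L, 1 / params$indel_mean_len)
    newb <- sample(DNA_BASES, len, replace = TRUE, prob = comp)
    lo <- if (pos == 1L) keys[1L] - 1 else keys[pos - 1L]
    hi <- if (pos > length(chars)) keys[length(keys)] + 1 else keys[pos]
    newk <- lo + (hi - lo) * sort(stats::runif(len))
    cand_chars <- append(chars, newb, after = pos - 1L)
    cand_keys <- append(keys, newk, after = pos - 1L)
    if (length(sel)) {
      before <- vapply(sel, function(s) window_count(chars, keys, s), integer(1))
      touches <- any(vapply(sel, function(s) any(newk >= s$key_lo & newk <= s$key_hi) ||
                              (pos > 1L && pos <= length(chars) &&
                                 in_sel(keys[pos - 1L]) && in_sel(keys[pos])),
                            logical(1)))
      if (touches && !acceptable(cand_chars, cand_keys, before)) next # reject
    }
    chars <- cand_chars; keys <- cand_keys
  }

  # --- deletions -----------------------------------------------------------
  n_del <- stats::rpois(1L, lam_ind * length(chars))
  for (e in seq_len(n_del)) {
    if (length(chars) <= 1L) break
    pos <- sample.int(length(chars), 1L)
    len <- min(1L + stats::rgeom(1L, 1 / params$indel_mean_len),
               length(chars) - pos + 1L)
    drop <- pos:(pos + len - 1L)
    if (length(sel) && any(in_sel(keys[drop]))) {
      before <- vapply(sel, function(s) window_count(chars, keys, s), integer(1))
      if (!acceptable(chars[-drop], keys[-drop], before)) next # reject
    }
    chars <- chars[-drop]; keys <- keys[-drop]
  }

  list(chars = chars, keys = keys)
}

#' Evolve a root sequence along a phylogeny
#'
#' Simulates neutral evolution (substitutions + indels, see [sim_params()])
#' from `root_seq` down every branch of the tree, optionally under
#' count-level selection inside target windows ([selection_spec()]).
#' Homology is tracked exactly, so the returned alignment is the true one.
#' Deterministic given `seed`.
#'
#' @param root_seq Root DNA string.
#' @param phy A [phylogeny()] with branch lengths.
#' @param params [sim_params()].
#' @param selection Optional list of [selection_spec()]s (root coordinates).
#' @param seed Integer seed.
#' @return A `sim_data` list: `phy`, `sequences` (named gapless strings for
#'   every node), `alignment` (named gapped rows over the true columns),
#'   `selection`, and `sel_keys` (key intervals of the selected windows).
#' @export
evolve <- function(root_seq, phy, params = sim_params(), selection = NULL,
                   seed = 1L) {
  stopifnot(inherits(phy, "phylogeny"), nchar(root_seq) >= 1L)
  if (inherits(selection, "selection_spec")) selection <- list(selection)
  chars0 <- strsplit(toupper(root_seq), "", fixed = TRUE)[[1L]]
  stopifnot(all(chars0 %in% DNA_BASES))
  keys0 <- as.numeric(seq_along(chars0))
  sel <- lapply(selection %||% list(), function(s) {
    stopifnot(inherits(s, "selection_spec"), s$end <= length(chars0))
    root_win <- paste(chars0[(s$start + 1L):s$end], collapse = "")
    if (count_sites(root_win, s$pwm) < s$k) {
      stop("selection infeasible: root window [", s$start, ",", s$end,
           ") holds fewer than k=", s$k, " predicted sites")
    }
    lm <- llr_matrix(s$pwm)
    list(key_lo = s$start + 1, key_hi = s$end, pwm = s$pwm, k = s$k,
         turnover = s$turnover, lm = lm, lm_rc = revcomp_lm(lm),
         threshold = s$pwm$threshold)
  })

  tr <- phy$tree
  ntip <- length(tr$tip.label)
  nms <- c(tr$tip.label, tr$node.label)
  states <- vector("list", ntip + tr$Nnode)
  states[[ntip + 1L]] <- list(chars = chars0, keys = keys0)
  edges <- stats::reorder(tr, "cladewise")
  elen <- edges$edge.length
  if (is.null(elen)) stop("tree has no branch lengths")
  withr::with_seed(seed, {
    for (j in seq_len(nrow(edges$edge))) {
      par <- edges$edge[j, 1L]; child <- edges$edge[j, 2L]
      states[[child]] <- mutate_branch(states[[par]], elen[j], params, sel)
    }
  })
  names(states) <- nms
  # True alignment over the union of keys.
  all_keys <- sort(unique(unlist(lapply(states, `[[`, "keys"))))
  alignment <- vapply(states, function(st) {
    row <- rep("-", length(all_keys))
    row[match(st$keys, all_keys)] <- st$chars
    paste(row, collapse = "")
  }, character(1))
  sequences <- vapply(states, function(st) paste(st$chars, collapse = ""),
                      character(1))
  structure(list(phy = phy, sequences = sequences, alignment = alignment,
                 states = states, selection = selection %||% list(),
                 sel_keys = sel),
            class = "sim_data")
}

#' A 9-leaf example phylogeny with named ancestors
#'
#' A mammal-like topology with branch lengths chosen so that per-branch
#' window divergences land around 5-15 percent at `scale = 1`; multiply
#' `scale` to push divergence up or down.
#'
#' @param scale Multiplier applied to all branch lengths.
#' @return A [phylogeny()] with reference leaf `hg`.
#' @export
example_tree <- function(scale = 1) {
  nwk <- paste0(
    "((((hg:0.08,pt:0.08)hp:0.05,(mm:0.14,rn:0.14)rod:0.08)prim:0.05,",
    "(cf:0.12,fc:0.12)car:0.08)bor:0.05,((bt:0.12,ss:0.12)art:0.08,",
    "md:0.22)lau:0.05)root;")
  tr <- ape::read.tree(text = nwk)
  tr$edge.length <- tr$edge.length * scale
  phylogeny(tr, reference = "hg")
}

#' Simulate a set of alignment blocks with optional planted binding loci
#'
#' Generates `n_blocks` independent blocks, each evolved from a random root
#' sequence of length `block_len`. The first `n_selected` blocks carry one
#' selected window of `sel_len` bp starting at `sel_offset`, seeded with `k`
#' spaced consensus matches of `sel_pwm` and maintained under count-level
#' selection with turnover. Blocks are laid end-to-end on one synthetic
#' reference chromosome.
#'
#' @param phy A [phylogeny()] with branch lengths.
#' @param n_blocks Number of blocks.
#' @param block_len Root sequence length per block.
#' @param params [sim_params()].
#' @param n_selected Number of blocks with a planted selected window.
#' @param sel_pwm Calibrated [pwm()] for the planted loci (required if
#'   `n_selected > 0`).
#' @param k Minimum maintained site count in selected windows.
#' @param sel_len,sel_offset Geometry of the selected window within a block.
#' @param turnover Passed to [selection_spec()].
#' @param chrom Reference chromosome name of the synthetic genome.
#' @param seed Integer seed.
#' @return List with `blocks` (a `block_set`; reference coordinates on the
#'   synthetic chromosome), `truth` (tibble of selected-window reference
#'   intervals, empty when `n_selected = 0`) and `sims` (list of `sim_data`).
#' @export
simulate_blocks <- function(phy, n_blocks, block_len = 300L,
                            params = sim_params(), n_selected = 0L,
                            sel_pwm = NULL, k = 2L, sel_len = 200L,
                            sel_offset = 50L, turnover = TRUE,
                            chrom = "chrSim", seed = 1L) {
  stopifnot(inherits(phy, "phylogeny"), n_blocks >= 1L,
            n_selected <= n_blocks, sel_offset + sel_len <= block_len)
  if (n_selected > 0L && is.null(sel_pwm)) {
    stop("n_selected > 0 requires sel_pwm")
  }
  ref <- phy$reference
  comp <- params$base_comp
  sims <- vector("list", n_blocks)
  block_rows <- vector("list", n_blocks)
  truth <- list()
  ref_cursor <- 0L
  for (i in seq_len(n_blocks)) {
    block_seed <- seed * 10000L + i  # < 2^31 for desk-scale n_blocks
    selected <- i <= n_selected
    root <- withr::with_seed(block_seed, {
      chars <- sample(DNA_BASES, block_len, replace = TRUE, prob = comp)
      if (selected) {
        cons <- consensus_seq(sel_pwm)
        w <- sel_pwm$width
        gap <- (sel_len - k * w) %/% (k + 1L)
        at <- sel_offset + gap * seq_len(k) + w * (seq_len(k) - 1L)
        for (s in at) chars[(s + 1L):(s + w)] <- strsplit(cons, "")[[1L]]
      }
      paste(chars, collapse = "")
    })
    selspec <- if (selected) {
      list(selection_spec(sel_offset, sel_offset + sel_len, sel_pwm,
                          k = k, turnover = turnover))
    } else NULL
    sim <- evolve(root, phy, params, selection = selspec,
                  seed = block_seed + 1L)
    sims[[i]] <- sim
    ref_len <- nchar(sim$sequences[[ref]])
    block_rows[[i]] <- tibble::tibble(
      block_id = i, chrom = chrom,
      ref_start = ref_cursor, ref_end = ref_cursor + ref_len,
      ref = ref, rows = list(sim$alignment)
    )
    if (selected) {
      st <- sim$states[[ref]]
      kint <- sim$sel_keys[[1L]]
      hit <- which(st$keys >= kint$key_lo & st$keys <= kint$key_hi)
      if (length(hit)) {
        truth[[length(truth) + 1L]] <- tibble::tibble(
          chrom = chrom,
          start = ref_cursor + min(hit) - 1L,
          end = ref_cursor + max(hit),
          name = paste0("locus", i), block_id = i)
      }
    }
    ref_cursor <- ref_cursor + ref_len
  }
  truth <- if (length(truth)) dplyr::bind_rows(truth) else {
    tibble::tibble(chrom = character(), start = integer(), end = integer(),
                   name = character(), block_id = integer())
  }
  list(blocks = new_block_set(dplyr::bind_rows(block_rows)),
       truth = truth, sims = sims)
}

# Modal base at each PWM position.
consensus_seq <- function(pwm) {
  paste(DNA_BASES[apply(pwm$mat, 2L, which.max)], collapse = "")
}

#' Write a simulated data set to disk as a self-contained fixture
#'
#' Emits the exact formats the alignment readers consume: a Newick tree, a
#' per-block gapped FASTA ([read_alignment_fasta()] format), a truth BED of
#' planted selected windows, and a `params.txt` with the generating
#' configuration. Byte-identical across runs with the same seed.
#'
#' @param dir Output directory (created if needed).
#' @param ... Arguments passed to [simulate_blocks()] (including `phy`,
#'   `n_blocks`, `seed`, ...).
#' @param phy Phylogeny, default [example_tree()].
#' @return Named character vector of the written paths, invisibly.
#' @export
make_fixture <- function(dir, phy = example_tree(), ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_blocks(phy = phy, ...)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             alignment = file.path(dir, "blocks.fa"),
             truth = file.path(dir, "truth.bed"),
             params = file.path(dir, "params.txt"))
  ape::write.tree(phy$tree, paths["tree"])
  con <- file(paths["alignment"], "w")
  for (i in seq_len(nrow(sim$blocks))) {
    b <- sim$blocks[i, ]
    writeLines(sprintf("# block id=%d chrom=%s start=%d end=%d ref=%s",
                       b$block_id, b$chrom, b$ref_start, b$ref_end, b$ref), con)
    rows <- b$rows[[1L]]
    writeLines(paste0(">", names(rows), "\n", rows), con)
  }
  close(con)
  write_bed(sim$truth[, c("chrom", "start", "end", "name")], paths["truth"])
  dots <- list(...)
  writeLines(paste0(names(dots), "=",
                    vapply(dots, function(x) paste(format(x), collapse = " "),
                           character(1))),
             paths["params"])
  invisible(paths)
}

#' Corrupt an alignment by re-placing gaps within local chunks
#'
#' Emulates misalignment noise: within non-overlapping chunks of `chunk`
#' alignment columns, a fraction `rate` of chunks have, in every
#' non-reference row, the row's bases re-placed at random column positions
#' (base order preserved, gaps moved). Every row's gapless sequence is
#' unchanged; only the homology statements inside corrupted chunks are
#' perturbed, as a real aligner's errors would.
#'
#' @param blocks A `block_set`.
#' @param rate Fraction of chunks corrupted.
#' @param chunk Chunk width in columns.
#' @param seed Integer seed.
#' @return The corrupted `block_set`.
#' @export
corrupt_alignment <- function(blocks, rate = 0.05, chunk = 10L, seed = 1L) {
  withr::with_seed(seed, {
    for (i in seq_len(nrow(blocks))) {
      rows <- blocks$rows[[i]]
      ref <- blocks$ref[i]
      m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
      rownames(m) <- names(rows)
      nc <- ncol(m)
      for (s in seq(1L, nc, by = chunk)) {
        if (stats::runif(1L) >= rate) next
        idx <- s:min(s + chunk - 1L, nc)
        for (r in setdiff(names(rows), ref)) {
          seg <- m[r, idx]
          bases <- seg[seg != "-"]
          if (length(bases) == 0L || length(bases) == length(seg)) next
          put <- sort(sample(length(seg), length(bases)))
          seg[] <- "-"
          seg[put] <- bases
          m[r, idx] <- seg
        }
      }
      blocks$rows[[i]] <- stats::setNames(
        apply(m, 1L, paste, collapse = ""), names(rows))
    }
  })
  blocks
}
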