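#' Non-normalized ensemble spread of committee predictions
#'
#' The scalar analogue of the curve spread metric: (mean + sd) - (mean - sd)
#' = 2 sd, with the population (ddof = 0) standard deviation and no
#' normalization by the mean — appropriate when predictions live on an
#' interval scale (e.g. reduction potentials in volts) where the mean may
#' be near zero.
#'
#' @param predictions numeric vector: one molecule's predictions across the
#'   committee members (length >= 2)
#' @return Non-negative scalar spread.
#' @export
nonnormalized_spread <- function(predictions) {
  stopifnot(length(predictions) >= 2, all(is.finite(predictions)))
  2 * sqrt(mean(predictions^2) - mean(predictions)^2)
}

# canonicalize a SMILES string; NA when unparseable (requires ChemmineOB)
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(suppressWarnings(suppressMessages(
      ChemmineOB::convertFormat("SMI", "CAN", source = s))),
      error = function(e) "")
    out <- sub("\\s.*$", "", trimws(out))
    if (nchar(out) == 0) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

template_positions <- c("3", "4", "5", "6", "7", "8")

build_substituted <- function(subs) {
  at <- function(sym, s) if (s == "") sym else paste0(sym, "(", s, ")")
  paste0("O=C1C(=O)", at("C", subs[["3"]]), "=", at("C", subs[["4"]]),
         "c2", at("c", subs[["5"]]), at("c", subs[["6"]]),
         at("c", subs[["7"]]), at("c", subs[["8"]]), "c21")
}

position_combos <- function(max_count, positions = template_positions) {
  combos <- list(character(0))
  for (k in seq_len(max_count)) {
    combos <- c(combos, combn(positions, k, simplify = FALSE))
  }
  combos
}

combo_label <- function(combo, prefix) {
  if (length(combo) == 0) "none" else
    paste0(prefix, paste(combo, collapse = ","))
}

#' Enumerate substituted quinones from the template
#'
#' Exhaustive placement of up to `max_each` hydroxyl and methyl groups on
#' the open ring positions (3-8, following the template's canonical atom
#' ranking; positions 1 and 2 carry the quinone carbonyls and are not
#' substitutable) of 1,2-naphthoquinone. Grid rows are hydroxyl placements
#' and columns methyl placements. Cells whose two placements collide on a
#' position, or whose structure fails to parse, are invalid and never
#' scored; symmetry duplicates (identical canonical structure seen in an
#' earlier cell) are flagged.
#'
#' @param template template SMILES (default 1,2-naphthoquinone)
#' @param positions substitutable position labels (subset of 3..8)
#' @param max_each maximum count per substituent type (default 2 each)
#' @param canonicalize use ChemmineOB canonicalization for validity and
#'   duplicate detection (default TRUE when the package is installed)
#' @return A `substitution_grid` tibble: `row`, `col` (placement labels),
#'   `hydroxyl`, `methyl` (comma-separated positions), `smiles`,
#'   `canonical`, `valid`, `duplicate`. Attribute `template` records the
#'   template and position numbering.
#' @export
enumerate_substituted <- function(template = "O=C1C(=O)C=Cc2ccccc21",
                                  positions = template_positions,
                                  max_each = 2,
                                  canonicalize =
                                    requireNamespace("ChemmineOB",
                                                     quietly = TRUE)) {
  stopifnot(all(positions %in% template_positions))
  if (canonicalize && is.na(canonical_smiles(template))) {
    stop("unparseable template: ", template)
  }
  oh <- position_combos(max_each, positions)
  me <- position_combos(max_each, positions)
  rows <- list()
  for (i in seq_along(oh)) {
    for (j in seq_along(me)) {
      clash <- length(intersect(oh[[i]], me[[j]])) > 0
      smiles <- NA_character_
      if (!clash) {
        subs <- setNames(rep("", 6), template_positions)
        subs[oh[[i]]] <- "O"
        subs[me[[j]]] <- "C"
        smiles <- build_substituted(subs)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        row = combo_label(oh[[i]], "OH"), col = combo_label(me[[j]], "Me"),
        hydroxyl = paste(oh[[i]], collapse = ","),
        methyl = paste(me[[j]], collapse = ","),
        smiles = smiles)
    }
  }
  g <- dplyr::bind_rows(rows)
  g$canonical <- g$smiles
  if (canonicalize) {
    ok <- !is.na(g$smiles)
    g$canonical[ok] <- canonical_smiles(g$smiles[ok])
  }
  g$valid <- !is.na(g$canonical)
  g$duplicate <- duplicated(g$canonical) & g$valid
  structure(g, class = c("substitution_grid", class(g)),
            template = template, positions = positions,
            max_each = max_each)
}

#' Spread heatmap over a substitution grid
#'
#' Scores every valid, non-duplicate cell with the non-normalized committee
#' spread and annotates training-set membership.
#'
#' @param grid an [enumerate_substituted()] grid
#' @param committee list of predictor functions, each mapping a structure
#'   string to one numeric prediction; a `training` attribute (character
#'   vector of canonical structures) marks training membership
#' @param top_k number of largest-spread structures to report
#' @return A `spread_heatmap`: the grid tibble with `spread` and
#'   `in_training` columns, attribute `top` (tibble of the `top_k`
#'   largest-spread novel structures).
#' @export
spread_heatmap <- function(grid, committee, top_k = 4) {
  stopifnot(length(committee) >= 2)
  training <- attr(committee, "training") %||% character(0)
  score <- grid$valid & !grid$duplicate
  structures <- grid$canonical[score]
  preds <- vapply(committee,
                  function(f) vapply(structures, f, numeric(1),
                                     USE.NAMES = FALSE),
                  numeric(length(structures)))
  preds <- matrix(preds, nrow = length(structures))
  spread <- rep(NA_real_, nrow(grid))
  spread[score] <- apply(preds, 1, nonnormalized_spread)
  out <- dplyr::mutate(grid, spread = spread,
                       in_training = .data$canonical %in% training)
  top <- dplyr::slice_head(
    dplyr::arrange(
      dplyr::filter(tibble::as_tibble(out), .data$valid, !.data$duplicate,
                    !.data$in_training),
      dplyr::desc(.data$spread)),
    n = top_k)
  structure(out, class = c("spread_heatmap", class(grid)), top = top)
}

#' Plot a spread heatmap
#'
#' Hydroxyl placements on the vertical axis, methyl placements on the
#' horizontal; invalid cells blank, training members marked with `*`.
#'
#' @param object a [spread_heatmap()]
#' @param ... unused
#' @return A ggplot object.
#' @export
autoplot.spread_heatmap <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d[d$valid & !d$duplicate, ],
                  ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$spread)) +
    ggplot2::geom_text(data = function(x) x[x$in_training, ],
                       label = "*", colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "spread") +
    ggplot2::labs(x = "methyl positions", y = "hydroxyl positions") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Rank candidate molecules for model training
#'
#' Orders novel (non-training) structures by descending spread — the
#' molecules the committee disagrees on most — and also emits the opposite
#' (low-spread) and a seeded random batch for downstream comparison.
#'
#' @param hm a [spread_heatmap()]
#' @param batch_size candidates per batch
#' @param seed seed for the random batch
#' @return A tibble: `canonical`, `spread`, `rank`, `batch` (`high`,
#'   `low`, or `random`; a structure may appear in more than one batch).
#' @export
rank_training_candidates <- function(hm, batch_size, seed = 1L) {
  d <- dplyr::filter(tibble::as_tibble(hm), .data$valid, !.data$duplicate,
                     !.data$in_training)
  d <- dplyr::arrange(d, dplyr::desc(.data$spread), .data$canonical)
  if (batch_size > nrow(d)) {
    warning("batch_size exceeds available candidates; returning all")
    batch_size <- nrow(d)
  }
  d <- dplyr::mutate(d, rank = dplyr::row_number())
  hi <- d[seq_len(batch_size), ]
  lo <- d[nrow(d) - rev(seq_len(batch_size)) + 1, ]
  set.seed(seed)
  rnd <- d[sample.int(nrow(d), batch_size), ]
  dplyr::bind_rows(
    dplyr::mutate(hi[c("canonical", "spread", "rank")], batch = "high"),
    dplyr::mutate(lo[c("canonical", "spread", "rank")], batch = "low"),
    dplyr::mutate(rnd[c("canonical", "spread", "rank")], batch = "random"))
}

# hashed character-trigram features of a structure string: a cheap stand-in
# for substructure fingerprints, sufficient for the toy committee fixture
hash_features <- function(s, n_buckets = 32) {
  v <- numeric(n_buckets)
  chars <- strsplit(s, "")[[1]]
  if (length(chars) < 3) return(v)
  for (i in seq_len(length(chars) - 2)) {
    tri <- paste0(chars[i], chars[i + 1], chars[i + 2])
    h <- sum(utf8ToInt(tri) * c(1L, 31L, 961L)) %% n_buckets + 1
    v[h] <- v[h] + 1
  }
  v
}

#' Toy cross-validated committee fixture
#'
#' A small ridge-regression committee on hashed substructure features,
#' trained on cross-validation folds of a labelled subset of the
#' substitution grid (synthetic labels: an additive position/substituent
#' model plus noise). Serves as the bundled stand-in for a production QSAR
#' committee: the interface is just a list of structure -> prediction
#' callables with a `training` attribute.
#'
#' @param grid an [enumerate_substituted()] grid
#' @param n_members committee size (cross-validation folds)
#' @param train_frac fraction of valid unique structures used as the
#'   labelled toy training set
#' @param seed RNG seed for labels, fold assignment, and noise
#' @return List of predictor functions with attributes `training`
#'   (canonical structures in the toy training set) and `labels`.
#' @export
toy_committee <- function(grid, n_members = 5, train_frac = 0.5,
                          seed = 1L) {
  set.seed(seed)
  d <- tibble::as_tibble(grid)
  d <- d[d$valid & !d$duplicate, ]
  n_oh <- lengths(strsplit(d$hydroxyl, ","))
  n_me <- lengths(strsplit(d$methyl, ","))
  labels <- 0.8 - 0.25 * n_oh + 0.1 * n_me + rnorm(nrow(d), 0, 0.03)
  idx <- sample.int(nrow(d), round(train_frac * nrow(d)))
  X <- t(vapply(d$canonical, hash_features, numeric(32)))
  folds <- cut(seq_along(idx), n_members, labels = FALSE)
  members <- lapply(seq_len(n_members), function(k) {
    tr <- idx[folds != k]
    Xtr <- X[tr, , drop = FALSE]
    ytr <- labels[tr]
    # ridge regression with a small penalty, closed form
    A <- crossprod(Xtr) + diag(0.5, ncol(X))
    beta <- solve(A, crossprod(Xtr, ytr))
    mu <- mean(ytr)
    function(structure) {
      as.numeric(hash_features(structure) %*% beta) +
        mu - as.numeric(colMeans(Xtr) %*% beta)
    }
  })
  structure(members, training = d$canonical[idx],
            labels = setNames(labels, d$canonical))
}
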