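#' Enumerate the full working-memory trial design
#'
#' Builds every distinct trial configuration of the sequential working-memory
#' task exactly once: the 6 orders of the three stimulus categories (face F,
#' banana B, chair C) crossed with 3 viewing perspectives per sequence
#' position, giving 6 x 3 x 3 x 3 = 162 unique trials. Trials are shuffled by
#' `seed` and partitioned into 6 runs of 27. The memory probe is balanced:
#' each sequence position is probed in a third of the trials and the correct
#' "same" answer occurs in exactly half. On "different" trials the probe keeps
#' the probed category but takes one of the two other perspectives, chosen
#' uniformly.
#'
#' @param seed Integer seed controlling trial order and probe assignment.
#' @return A data frame with one row per trial: `trial_id`, `run_id`,
#'   `cat_1..3`, `persp_1..3`, `probe_position`, `probe_category`,
#'   `probe_perspective`, `probe_same`, plus empty response slots
#'   (`detail_response`, `detail_rt`, `order_response`, `order_rt`).
#' @export
enumerate_design <- function(seed = 1L) {
  perms <- list(c("F","B","C"), c("F","C","B"), c("B","F","C"),
                c("B","C","F"), c("C","F","B"), c("C","B","F"))
  grid <- expand.grid(perm = seq_along(perms),
                      p1 = PERSPECTIVE_LEVELS, p2 = PERSPECTIVE_LEVELS,
                      p3 = PERSPECTIVE_LEVELS,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)  # 162
  cats <- t(vapply(grid$perm, function(i) perms[[i]], character(3)))
  with_seed(seed, {
    ord <- sample.int(n)
    design <- data.frame(
      trial_id = seq_len(n),
      run_id = rep(1:6, each = n / 6),
      cat_1 = cats[ord, 1], cat_2 = cats[ord, 2], cat_3 = cats[ord, 3],
      persp_1 = grid$p1[ord], persp_2 = grid$p2[ord], persp_3 = grid$p3[ord],
      stringsAsFactors = FALSE
    )
    design$probe_position <- sample(rep(1:3, length.out = n))
    design$probe_same <- sample(rep(c(TRUE, FALSE), length.out = n))
    probed_cat <- vapply(seq_len(n), function(i)
      design[[paste0("cat_", design$probe_position[i])]][i], character(1))
    probed_persp <- vapply(seq_len(n), function(i)
      design[[paste0("persp_", design$probe_position[i])]][i], character(1))
    other_persp <- vapply(probed_persp, function(p)
      sample(setdiff(PERSPECTIVE_LEVELS, p), 1L), character(1))
    design$probe_category <- probed_cat
    design$probe_perspective <- ifelse(design$probe_same, probed_persp, other_persp)
    design$detail_response <- NA
    design$detail_rt <- NA_real_
    design$order_response <- NA_integer_
    design$order_rt <- NA_real_
    design
  })
}

# Category shown at each sequence position of one trial, as a length-3 vector.
trial_sequence <- function(design, i) {
  c(design$cat_1[i], design$cat_2[i], design$cat_3[i])
}
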