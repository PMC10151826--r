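#' Generate small assay fixture tables with known ground truth
#'
#' Emits tables in the exact input dialects consumed by the bench-assay and
#' survival quantifiers, with the generating truth attached as attribute
#' `"truth"`. Kinds:
#'
#' * `"climbing"`: one row per trial with chamber counts `n0..n5`
#'   (`params$counts`, a vector or 6-column matrix, is echoed unchanged).
#' * `"cafe"`: per-vial capillary displacements. `params`:
#'   `true_ul_per_fly`, `n_vials`, `n_flies`, `n_capillaries`,
#'   `calibration_mm_per_ul`, `duration_h`, `noise_sd_mm`.
#' * `"qpcr"`: long plate of Ct triplicates. `params`: `fold_changes`
#'   (named per group, control = 1), `n_per_group`, `target_gene`,
#'   `reference_gene`, `control_group`, `base_ct`, `ref_ct`, `noise_sd`
#'   (replicate spread; 0 gives CV = 0).
#' * `"survival"`: subject-level death/censoring table. `params`: either
#'   `times` + `events` (+ optional `groups`) echoed directly, or per-group
#'   exponential draws via `n`, `rate` (named vectors), `censor_time`.
#'
#' @param kind One of `"climbing"`, `"cafe"`, `"qpcr"`, `"survival"`.
#' @param params Named list of parameters (see above; all have defaults).
#' @param seed Integer seed for the noisy kinds.
#' @return A `data.frame` in the consumer's input dialect, with attribute
#'   `"truth"`.
#' @examples
#' make_assay_fixtures("qpcr", list(noise_sd = 0), seed = 1)
#' @export
make_assay_fixtures <- function(kind, params = list(), seed = 1L) {
  kind <- as.character(kind)
  if (!kind %in% c("climbing", "cafe", "qpcr", "survival"))
    mrdam_stop(sprintf("unknown fixture kind '%s'", kind),
               "mrdam_validation_error")
  p <- params
  switch(kind,
    climbing = {
      counts <- p$counts %||% c(2, 3, 5, 4, 1, 0)
      counts <- matrix(counts, ncol = 6L, byrow = TRUE)
      colnames(counts) <- paste0("n", 0:5)
      out <- data.frame(trial = seq_len(nrow(counts)), counts)
      attr(out, "truth") <- list(index = apply(counts, 1L, climbing_index))
      out
    },
    cafe = with_seed(seed, {
      n_vials <- p$n_vials %||% 5L
      n_flies <- p$n_flies %||% 8L
      n_cap <- p$n_capillaries %||% 6L
      calib <- p$calibration_mm_per_ul %||% 6.5
      dur <- p$duration_h %||% 19
      true_ul <- p$true_ul_per_fly %||% 1.2
      noise <- p$noise_sd_mm %||% 0
      per_cap_mm <- true_ul * n_flies / n_cap * calib
      disp <- matrix(pmax(stats::rnorm(n_vials * n_cap, per_cap_mm, noise), 0),
                     nrow = n_vials)
      colnames(disp) <- paste0("cap", seq_len(n_cap))
      out <- data.frame(vial = seq_len(n_vials), n_flies = n_flies,
                        duration_h = dur,
                        calibration_mm_per_ul = calib, disp)
      attr(out, "truth") <- list(ul_per_fly = true_ul)
      out
    }),
    qpcr = with_seed(seed, {
      fc <- p$fold_changes %||% c(control = 1, treatment = 2)
      npg <- p$n_per_group %||% 4L
      target <- p$target_gene %||% "trbl"
      ref <- p$reference_gene %||% "rp49"
      ctrl <- p$control_group %||% names(fc)[1]
      base_ct <- p$base_ct %||% 24
      ref_ct <- p$ref_ct %||% 18
      noise <- p$noise_sd %||% 0.05
      rows <- list()
      for (g in names(fc)) for (i in seq_len(npg)) {
        sid <- sprintf("%s_%02d", g, i)
        # fold change fc => dCt shifted by -log2(fc) relative to control
        tgt_mean <- base_ct - log2(fc[[g]])
        for (rep in 1:3) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, group = g, gene = target,
            ct = stats::rnorm(1, tgt_mean, noise), stringsAsFactors = FALSE)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, group = g, gene = ref,
            ct = stats::rnorm(1, ref_ct, noise), stringsAsFactors = FALSE)
        }
      }
      out <- do.call(rbind, rows)
      attr(out, "truth") <- list(fold_changes = fc, control_group = ctrl,
                                 target_gene = target, reference_gene = ref)
      out
    }),
    survival = with_seed(seed, {
      if (!is.null(p$times)) {
        times <- p$times
        events <- p$events %||% rep(1L, length(times))
        groups <- p$groups %||% rep("all", length(times))
        out <- data.frame(subject_id = sprintf("s%03d", seq_along(times)),
                          time = times, event = as.integer(events),
                          group = groups, stringsAsFactors = FALSE)
        attr(out, "truth") <- list(times = times, events = events)
        return(out)
      }
      n <- p$n %||% c(control = 20L, treated = 20L)
      rate <- p$rate %||% c(control = 0.1, treated = 0.1)
      censor <- p$censor_time %||% Inf
      rows <- lapply(names(n), function(g) {
        t_true <- stats::rexp(n[[g]], rate[[g]])
        data.frame(subject_id = sprintf("%s_%03d", g, seq_len(n[[g]])),
                   time = pmin(t_true, censor),
                   event = as.integer(t_true <= censor),
                   group = g, stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, rows)
      attr(out, "truth") <- list(rate = rate, censor_time = censor)
      out
    })
  )
}
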