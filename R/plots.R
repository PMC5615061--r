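# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted dose-response curve
#'
#' Points are the observed replicates; the line is the fitted 4PL curve
#' on a log-dose axis.
#'
#' @param object A `fourpl_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fourpl_fit
#' @export
autoplot.fourpl_fit <- function(object, ...) {
  dat <- object$data
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$dose_uM,
                                         y = .data$response)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (µM)", y = "fraction of control activity")
  if (object$converged && !object$right_censored) {
    grid <- exp(seq(log(min(dat$dose_uM)), log(max(dat$dose_uM)),
                    length.out = 100))
    curve <- tibble::tibble(
      dose_uM = grid,
      response = fourpl_response(grid, object$bottom, object$top,
                                 object$ic50, object$hill)
    )
    p <- p + ggplot2::geom_line(data = curve, colour = "steelblue") +
      ggplot2::geom_vline(xintercept = object$ic50, linetype = "dashed",
                          colour = "grey40")
  }
  p
}

#' Plot a consensus ranking
#'
#' Mean ensemble affinity against rank; optional highlighting of known
#' actives and the top-K cut.
#'
#' @param object A [consensus_rank()] table.
#' @param active_ids Optional ligand ids to highlight.
#' @param k Optional top-K cut to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot consensus_result
#' @export
autoplot.consensus_result <- function(object, active_ids = NULL, k = NULL,
                                      ...) {
  dat <- dplyr::mutate(
    tibble::as_tibble(object),
    active = if (is.null(active_ids)) FALSE
             else .data$ligand_id %in% active_ids
  )
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank,
                                         y = .data$mean_affinity)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$active), size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick"),
                                 guide = if (is.null(active_ids)) "none"
                                         else "legend") +
    ggplot2::labs(x = "consensus rank",
                  y = "mean ensemble affinity (kcal/mol)",
                  colour = "active")
  if (!is.null(k))
    p <- p + ggplot2::geom_vline(xintercept = k + 0.5, linetype = "dashed")
  p
}

#' Tile plot of a contact fingerprint
#'
#' Residues against pose with hydrogen-bond / polar-contact status and
#' the per-residue interaction energy as fill.
#'
#' @param fp A [contact_fingerprint()] table (rows from one or more
#'   poses).
#' @return A ggplot.
#' @export
plot_fingerprint <- function(fp) {
  dat <- dplyr::mutate(
    tibble::as_tibble(fp),
    residue = paste0(.data$resname, .data$resno),
    status = dplyr::case_when(
      .data$has_hbond ~ "H-bond",
      .data$has_polar ~ "polar",
      TRUE ~ "none"
    )
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$residue, y = .data$pose_id)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$energy_kcal_mol),
                       colour = "white") +
    ggplot2::geom_point(data = dplyr::filter(dat, .data$status != "none"),
                        ggplot2::aes(shape = .data$status), size = 2) +
    ggplot2::scale_shape_manual(values = c(`H-bond` = 8, polar = 1)) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "E (kcal/mol)", shape = NULL)
}
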