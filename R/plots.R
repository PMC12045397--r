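# ggplot2 views of probe results

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a probe result
#'
#' Dispatches on the probe that produced the result: violins of the score
#' distributions for the doubling, multiplicity, imperfect-repeat and RNA
#' context probes; a heat map for the flip profile; a tile map of median local
#' pseudo-perplexity for the needle sweep; positional line profiles for the
#' skip and contra-lateral probes; and condition-wise entropy distributions
#' for the equivalent-mask probe.
#'
#' @param object A `probe_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.probe_result <- function(object, ...) {
  probe <- attr(object, "probe")
  tbl <- tibble::as_tibble(object)
  gg <- ggplot2::ggplot
  aes <- ggplot2::aes
  switch(probe,
    doubling = gg(tbl, aes(x = .data$condition, y = .data$value)) +
      ggplot2::geom_violin(fill = "grey85") +
      ggplot2::geom_jitter(width = 0.08, alpha = 0.4, size = 0.8) +
      ggplot2::labs(x = NULL, y = "pseudo-perplexity",
                    title = "Doubling experiment"),
    multiplicity = gg(tbl, aes(x = factor(.data$multiplicity),
                               y = .data$value)) +
      ggplot2::geom_violin(fill = "grey85") +
      ggplot2::facet_wrap(~unit_size, labeller = ggplot2::label_both) +
      ggplot2::labs(x = "multiplicity", y = "pseudo-perplexity"),
    imperfect_repeat = gg(tbl, aes(x = factor(.data$rate), y = .data$value,
                                   fill = .data$condition)) +
      ggplot2::geom_violin(position = ggplot2::position_dodge(0.8)) +
      ggplot2::labs(x = "mutation rate", y = "local pseudo-perplexity"),
    rna_context = gg(tbl, aes(x = .data$context, y = .data$value)) +
      ggplot2::geom_violin(fill = "grey85") +
      ggplot2::labs(x = "appended context", y = "pseudo-perplexity"),
    equivalent_mask = gg(tbl, aes(x = .data$condition, y = .data$entropy)) +
      ggplot2::geom_violin(fill = "grey85") +
      ggplot2::labs(x = NULL, y = "entropy (nats)") +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1)),
    flip_profile = gg(tbl, aes(x = .data$predicted_symbol,
                               y = .data$substituted_symbol,
                               fill = .data$probability)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(x = "predicted symbol", y = "substituted symbol"),
    needle_sweep = tbl |>
      dplyr::group_by(.data$needle_size, .data$haystack_size) |>
      dplyr::summarise(median_ppl = stats::median(.data$value),
                       .groups = "drop") |>
      gg(aes(x = factor(.data$haystack_size), y = factor(.data$needle_size),
             fill = .data$median_ppl)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(direction = -1) +
      ggplot2::labs(x = "haystack size", y = "needle size",
                    fill = "median local PPL"),
    skip = tbl |>
      tidyr::pivot_longer(c("p_equivalent", "p_correct"),
                          names_to = "profile", values_to = "mass") |>
      dplyr::group_by(.data$condition, .data$position, .data$profile) |>
      dplyr::summarise(mass = mean(.data$mass), .groups = "drop") |>
      gg(aes(x = .data$position, y = .data$mass, colour = .data$profile)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~condition) +
      ggplot2::labs(y = "mean probability mass"),
    contralateral = tbl |>
      dplyr::group_by(.data$position) |>
      dplyr::summarise(preference = mean(.data$preference), .groups = "drop") |>
      gg(aes(x = .data$position, y = .data$preference)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::geom_line() +
      ggplot2::labs(y = "p(right) - p(left)"),
    stop(sprintf("no autoplot defined for probe '%s'", probe), call. = FALSE)
  )
}

#' Plot validation-loss curves of an embedding regression
#'
#' @param object An `embedding_regression` object.
#' @param ... Unused.
#' @return A ggplot object of run-averaged validation loss per group.
#' @export
autoplot.embedding_regression <- function(object, ...) {
  object$curves |>
    dplyr::filter(.data$split == "validation") |>
    dplyr::group_by(.data$group, .data$epoch) |>
    dplyr::summarise(loss = mean(.data$loss), .groups = "drop") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$epoch, y = .data$loss,
                                 colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "validation cross-entropy (nats)")
}
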