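# autoplot() methods for the result objects.  All return ggplot objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.pes_scan <- function(object, ...) {
  thr <- attr(object, "thresholds")
  dat <- as_tibble(object) %>%
    filter(!is.na(.data$p_empirical)) %>%
    mutate(neglog_p = -log10(.data$p_empirical))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$set_id, y = .data$neglog_p,
                                    colour = .data$phase)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(thr$scan), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(-log[10](p[empirical])),
                  title = "Pathway polygenic-effect-score scan",
                  subtitle = sprintf("dashed: Bonferroni %.3g", thr$scan)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @export
autoplot.burden_scan <- function(object, ...) {
  dat <- as_tibble(object) %>% filter(!is.na(.data$p))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$set_id,
                                    y = -log10(.data$p),
                                    shape = factor(.data$maf_max),
                                    colour = .data$category)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  shape = "MAF ceiling", colour = "category",
                  title = "Gene-set rare-variant burden (SKAT-O)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @export
autoplot.community_partition <- function(object, ...) {
  sizes <- attr(object, "sizes")
  dat <- tibble(community = factor(names(sizes), levels = names(sizes)),
                size = as.integer(sizes))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$community, y = .data$size)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "community", y = "genes",
                  title = sprintf("Expression communities (Q = %.3f)",
                                  attr(object, "modularity"))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.celltype_scan <- function(object, ...) {
  dec <- attr(object, "deciles")
  ggplot2::ggplot(dec, ggplot2::aes(x = .data$decile,
                                    y = .data$r2_liability,
                                    colour = .data$phase)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~cell_type) +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(x = "specificity decile (1 = least specific)",
                  y = expression(liability~R^2),
                  title = "Polygenic R2 by cell-type specificity decile") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.smr_scan <- function(object, ...) {
  thr <- attr(object, "thresholds")
  dat <- as_tibble(object) %>% filter(!is.na(.data$p_smr))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$b_smr, y = -log10(.data$p_smr),
                                    colour = .data$pass)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(thr$smr), linetype = "dashed") +
    ggplot2::labs(x = expression(b[SMR]~(log~OR~per~SD~expression)),
                  y = expression(-log[10](p[SMR])),
                  colour = "passes SMR + HEIDI",
                  title = "SMR gene prioritization") +
    ggplot2::theme_minimal()
}
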