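# Fixtures are built in code. A "flat chart" is a fully compliant 20-tooth
# chart with constant measurements, convenient to perturb site by site.

FLAT_TEETH <- c(11:17, 21:27, 31:33, 41:43)  # 20 teeth

make_flat_chart <- function(id = "T01", teeth = FLAT_TEETH,
                            cal = 2L, pd = 2L, bop = 0L, pli = 0L,
                            mobility = 0L) {
  uni <- site_universe()
  d <- uni[uni$tooth %in% teeth, c("tooth", "surface", "position")]
  data.frame(patient_id = id, d,
             cal = as.integer(cal), pd = as.integer(pd),
             bop = as.integer(bop), pli = as.integer(pli),
             mobility = as.integer(mobility),
             stringsAsFactors = FALSE)
}

# set a value at one site of a chart
set_site <- function(chart, tooth, surface, position, col, value) {
  i <- chart$tooth == tooth & chart$surface == surface &
    chart$position == position
  stopifnot(sum(i) == 1L)
  chart[i, col] <- as.integer(value)
  chart
}

# the six planted winner tooth types of the "paper-2020" preset
PLANTED_TYPES <- c("max5", "max4", "max3", "max2", "max1", "mand4")

planted_sites <- function() {
  ref <- reference_site_params("cal")
  uni <- site_universe()
  uni[paste(uni$tooth_type, uni$surface, uni$position) %in%
        paste(ref$tooth_type, ref$surface, ref$position), ]
}

# direct maximizer of the 2-item dichotomous marginal likelihood:
# independent of the EM path (joint Nelder-Mead over all 4 parameters,
# multi-start)
direct_2pl_loglik <- function(X, quad = quadrature_spec()) {
  negll <- function(par) {
    a <- exp(par[c(1, 3)]); b <- par[c(2, 4)]
    L <- rep(1, length(quad$nodes)) %o% rep(1, nrow(X))
    for (j in 1:2) {
      p1 <- plogis(a[j] * (quad$nodes - b[j]))
      P <- cbind(1 - p1, p1)
      L <- L * P[, X[, j] + 1L]
    }
    -sum(log(colSums(L * quad$weights)))
  }
  starts <- list(c(0, 0, 0, 0), c(log(2), 0.5, log(2), -0.5),
                 c(log(0.5), -1, log(1.5), 1))
  best <- Inf
  for (s in starts) {
    o <- optim(s, negll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
    o <- optim(o$par, negll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
    best <- min(best, o$value)
  }
  -best
}

# exhaustive concordant-pair AUC (ties count 1/2)
pair_count_auc <- function(score, outcome) {
  pos <- score[outcome == 1]; neg <- score[outcome == 0]
  grid <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(grid)
}
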