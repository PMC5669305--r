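# Enumeration oracle: conditional log-likelihood of the two-period
# fixed-effects logit, summing over all within-household outcome
# arrangements with the observed household total. eta is the linear
# predictor x * beta per observation (household intercepts cancel).
enum_cloglik <- function(y, eta, hh) {
  ll <- 0
  for (h in unique(hh)) {
    idx <- which(hh == h)
    yh <- y[idx]; eh <- eta[idx]
    tot <- sum(yh)
    arrangements <- which(rowSums(expand.grid(0:1, 0:1)) == tot)
    grid <- as.matrix(expand.grid(0:1, 0:1))[arrangements, , drop = FALSE]
    denom <- sum(exp(grid %*% eh))
    ll <- ll + sum(yh * eh) - log(denom)
  }
  ll
}

clogit_fixture <- function() {
  # 3 switcher households + 1 non-switcher, differing treatment exposure
  dist <- c(1, 1, 2, 2)
  p <- toy_panel(4, dist, dist, function(hh, wave) 0)
  p$cough <- c(0, 1, 0, 1,   # wave 0
               1, 0, 1, 1)   # wave 1
  ex <- toy_exposures(2, coal = c(2L, 0L))
  list(panel = p, exposures = ex)
}
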