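# shared fixtures built in code

ref_params <- function(Ks = NA_real_, tau = NA_real_) {
  kosugi_params(theta_r = 0.05, theta_s = 0.50, w = 0.7,
                hm1 = 50, sigma1 = 0.8, hm2 = 2000, sigma2 = 1.2,
                Ks = Ks, tau = tau)
}

# printed soil-physics table of the field trial: BD, porosity, texture per
# treatment x depth (means)
table2 <- data.frame(
  depth = rep(c("1-6", "15-20"), each = 3),
  treatment = rep(c("control", "basalt", "lime"), 2),
  BD = c(1.32, 1.33, 1.28, 1.47, 1.42, 1.38),
  phi = c(0.50, 0.50, 0.52, 0.44, 0.46, 0.48),
  sand = c(24, 29, 14, 20, 23, 15),
  silt = c(65, 59, 67, 67, 62, 64),
  clay = c(11, 12, 19, 13, 15, 21))

random_valid_params <- function() {
  hm <- sort(10^runif(2, 0.2, 4.5))
  tr <- runif(1, 0, 0.15)
  kosugi_params(theta_r = tr, theta_s = runif(1, tr + 0.2, 0.65),
                w = runif(1, 0.05, 0.95),
                hm1 = hm[1], sigma1 = runif(1, 0.3, 2.5),
                hm2 = hm[2], sigma2 = runif(1, 0.3, 2.5),
                Ks = 10^runif(1, -1, 3), tau = runif(1, -1, 2))
}
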