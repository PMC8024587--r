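# Phantom constructors shared by the tractography and connectome tests.

straight_bundle_phantom <- function(fa_target = 0.8, background_fa = 0.1,
                                    noise_sd = 0) {
  path <- cbind(seq(3, 22), 8, 5)
  gen_tensor_phantom(phantom_spec(
    grid_shape = c(25, 15, 9),
    bundles = list(list(path = path, radius = 2, fa_target = fa_target)),
    background_fa = background_fa, noise_sd = noise_sd, seed = 1
  ))
}

quarter_circle_phantom <- function(r = 20, fa_target = 0.7) {
  theta <- seq(pi, pi / 2, length.out = 40)
  path <- cbind(25 + r * cos(theta), 5 + r * sin(theta), 5)
  gen_tensor_phantom(phantom_spec(
    grid_shape = c(30, 30, 9),
    bundles = list(list(path = path, radius = 2, fa_target = fa_target)),
    background_fa = 0.05, seed = 1
  ))
}

two_bundle_phantom <- function() {
  gen_tensor_phantom(phantom_spec(
    grid_shape = c(25, 22, 9),
    bundles = list(
      list(path = cbind(seq(3, 22), 5, 5), radius = 1.5, fa_target = 0.8),
      list(path = cbind(seq(3, 22), 16, 5), radius = 1.5, fa_target = 0.7)
    ),
    background_fa = 0.1, seed = 1
  ))
}

# Two abutting blocks whose principal directions differ by `angle_deg`;
# returns a tensor_volume (no bundle machinery, directions set by hand).
kink_phantom <- function(angle_deg = 60, fa = 0.7) {
  dm <- c(20L, 11L, 7L)
  data <- array(0, c(dm, 6L))
  bg <- wmnet:::tensor_from_fa(0.05, c(1, 0, 0))
  for (c6 in 1:6) data[, , , c6] <- bg[c6]
  ang <- angle_deg * pi / 180
  t1 <- wmnet:::tensor_from_fa(fa, c(1, 0, 0))
  t2 <- wmnet:::tensor_from_fa(fa, c(cos(ang), sin(ang), 0))
  for (i in 1:10) for (j in 4:8) for (k in 3:5) data[i, j, k, ] <- t1
  for (i in 11:20) for (j in 4:8) for (k in 3:5) data[i, j, k, ] <- t2
  tensor_volume(data)
}
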