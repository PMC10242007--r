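# shared fixtures for the suite: tiny sites, tiny model configs, and a toy
# 1-parameter quadratic objective for the federated-algebra tests

tiny_site <- function(n0 = 2, n1 = 3, seed = 1L, ...) {
  site_spec(site_id = paste0("t", seed), n_class0 = n0, n_class1 = n1,
            seed = seed, ...)
}

mini_model_config <- function(seed = 7L, ...) {
  model_config("tiny", input_size = 8,
               channel_widths = c(2, 2, 2, 2, 2, 2, 2),
               bilinear_dim = 3, fc_dims = c(4, 3), seed = seed, ...)
}

# scalar quadratic objective L(w) = 0.5 * (w - b)^2 per "observation";
# data is a list with `b` (targets) used full-batch
quad_objective <- function() {
  list(
    init = function(seed) param_set(list(w = 0)),
    loss_grad = function(params, data, idx) {
      b <- mean(data$b[idx])
      list(loss = 0.5 * (params$w - b)^2,
           grad = param_set(list(w = params$w - b)))
    },
    predict = function(params, data)
      cbind(rep(0.5, length(data$b)), rep(0.5, length(data$b))),
    n_obs = function(data) length(data$b)
  )
}

random_param_set <- function(seed = 1) {
  set.seed(seed)
  param_set(list(a = array(rnorm(24), c(2, 3, 4)),
                 b = matrix(rnorm(6), 2, 3),
                 c = rnorm(5)))
}
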