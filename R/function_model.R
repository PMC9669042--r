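#' Wrap a prediction function as a model object
#'
#' Adapts an arbitrary `function(records) -> predictions` so it can be used
#' wherever a fitted surrogate is expected ([pdp_ice()], [ale()],
#' [water_response()], [recommend_water()], ...). Useful for closed-form
#' response models and for cross-checking the interpretation and inversion
#' machinery against analytically known answers.
#'
#' @param fun function taking a data.frame of records and returning a
#'   numeric prediction per row.
#' @param features character vector of feature names the function reads.
#' @return A `function_model` with a `predict` method.
#' @examples
#' m <- function_model(function(d) 800 - 0.1 * d$plain_water, "plain_water")
#' predict(m, data.frame(plain_water = c(0, 1000)))
#' @export
function_model <- function(fun, features) {
  stopifnot(is.function(fun), is.character(features), length(features) >= 1)
  structure(list(fun = fun, features = features), class = "function_model")
}

#' @export
predict.function_model <- function(object, newdata, ...) {
  p <- object$fun(as.data.frame(newdata))
  stopifnot(is.numeric(p))
  as.numeric(p)
}
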