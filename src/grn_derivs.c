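/* Right-hand side of the regulatory-network ODE system, in the form deSolve
 * expects from compiled code.  One generic derivative function serves every
 * structure in the combinatorial family: the structure (which Hill factors
 * each gene's production term uses) is encoded in the parameter vector.
 *
 * Parameter vector layout (fixed length GRN_NPARMS, padded with zeros):
 *   p[0] = ng            number of modelled genes (2 or 3)
 *   p[1] = kt            translation rate (1 in the symmetry-reduced model)
 *   p[2] = km            shared mRNA degradation rate
 *   p[3] = kp            shared protein degradation rate
 *   then per gene g = 0..ng-1, a block of 12 doubles at 4 + 12 g:
 *     [0] gene_id        1 = eud-1/E, 2 = nhr-40/N, 3 = sult-1/S
 *     [1] alpha          basal transcription rate
 *     [2] ktg            maximal regulated transcription rate
 *     [3] nfac           number of Hill factors in the production term (0-2;
 *                        0 means no regulated production at all)
 *     [4] f1_reg  [5] f1_sign (0 act / 1 rep)  [6] f1_exp (1 or 2)  [7] f1_K
 *     [8] f2_reg  [9] f2_sign                 [10] f2_K  [11] spare
 *
 * State vector: y[0..ng-1] mRNA, y[ng..2ng-1] protein, same gene order.
 */

#include <R.h>

#define GRN_NPARMS 64

static double p[GRN_NPARMS];

void grn_init(void (*odeparms)(int *, double *))
{
  int N = GRN_NPARMS;
  odeparms(&N, p);
}

static double hill(double x, double K, int sign)
{
  return sign == 0 ? x / (K + x) : K / (K + x);
}

void grn_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
  int ng = (int) p[0];
  double kt = p[1], km = p[2], kp = p[3];
  double prot[4] = {0.0, 0.0, 0.0, 0.0};
  int g;

  for (g = 0; g < ng; g++)
    prot[(int) p[4 + 12 * g]] = y[ng + g];

  for (g = 0; g < ng; g++) {
    const double *b = p + 4 + 12 * g;
    int nfac = (int) b[3];
    double F = 0.0;
    if (nfac > 0) {
      F = hill(prot[(int) b[4]], b[7], (int) b[5]);
      if ((int) b[6] == 2)
        F *= F;
      if (nfac == 2)
        F *= hill(prot[(int) b[8]], b[10], (int) b[9]);
    }
    ydot[g]      = b[1] + b[2] * F - km * y[g];
    ydot[ng + g] = kt * y[g] - kp * y[ng + g];
  }
}
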