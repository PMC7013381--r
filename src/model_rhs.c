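/* Compiled right-hand side of the five-compartment infection model,
   in the deSolve compiled-code interface. Parameter order must match
   the R-side vector built in acr_simulate():
   a, A, B, rho, phi, gamma, r, k, m. */
#include <R.h>

static double parms[9];
#define P_a     parms[0]
#define P_A     parms[1]
#define P_B     parms[2]
#define P_rho   parms[3]
#define P_phi   parms[4]
#define P_gamma parms[5]
#define P_r     parms[6]
#define P_k     parms[7]
#define P_m     parms[8]

void acr_initmod(void (*odeparms)(int *, double *))
{
    int n = 9;
    odeparms(&n, parms);
}

void acr_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double W = y[0], R = y[1], S = y[2], V1 = y[3], V2 = y[4];
    double N = W + R + S;
    double V = V1 + V2;
    double growth = P_r * (1.0 - P_k * N);

    ydot[0] = growth * W - (P_a * V + P_m) * W;
    ydot[1] = P_A * P_a * V * W + growth * R
              - (P_a * (1.0 - P_rho) * V1 + P_m) * R + P_gamma * S;
    ydot[2] = P_a * (1.0 - P_rho) * (1.0 - P_phi) * V1 * R
              - (P_a * V + P_m + P_gamma) * S;
    ydot[3] = P_a * (1.0 - P_rho) * P_phi * P_B * V1 * R
              + P_a * P_B * V1 * (S + (1.0 - P_A) * W) - P_a * N * V1;
    ydot[4] = P_a * P_B * V2 * (S + (1.0 - P_A) * W) - P_a * N * V2;
}
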