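/* Compiled right-hand side of the bioreactor mass balances, in the deSolve
 * compiled-code calling convention.
 *
 * Parameter block (fixed length, packed by .pack_parms() on the R side):
 *   [0] r_X_max  [1] k_N  [2] y_X_N  [3] r_p_max  [4] k_p  [5] k_pd
 *   [6] mode (0 batch/event segment, 1 fed-batch, 2 semi-continuous rate)
 *   [7] D  [8] F  [9] c_N_f
 *   [10] n_grid  [11] c_max  [12..] phi grid
 *
 * phi is the volume-averaged Monod-in-light factor tabulated on a uniform
 * biomass grid [0, c_max]; it already contains k_I, sigma_X and I0.
 *
 * States: y = (c_X, c_N, c_P, V, H_X, H_P); the last two accumulate
 * harvested biomass (g) and product (mg) under continuous dilution.
 */

#include <R.h>

#define PARMS_LEN 3072

static double parms[PARMS_LEN];

void mossreactor_init(void (*odeparms)(int *, double *))
{
    int n = PARMS_LEN;
    odeparms(&n, parms);
}

void mossreactor_derivs(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    const double r_X_max = parms[0], k_N = parms[1], y_X_N = parms[2];
    const double r_p_max = parms[3], k_p = parms[4], k_pd = parms[5];
    const int mode = (int) parms[6];
    const double D_conf = parms[7], F_flow = parms[8], c_N_f = parms[9];
    const int n_grid = (int) parms[10];
    const double c_max = parms[11];
    const double *phi = parms + 12;

    double c_X = y[0] > 0 ? y[0] : 0;
    double c_N = y[1] > 0 ? y[1] : 0;
    double c_P = y[2] > 0 ? y[2] : 0;
    double V = y[3];

    /* light-limited growth factor: linear interpolation on the phi grid */
    double phi_c;
    if (c_X >= c_max) {
        phi_c = phi[n_grid - 1];
    } else {
        double pos = c_X / c_max * (n_grid - 1);
        int i = (int) pos;
        if (i >= n_grid - 1) i = n_grid - 2;
        double frac = pos - i;
        phi_c = phi[i] + frac * (phi[i + 1] - phi[i]);
    }

    double m_N = (c_N + k_N > 0) ? c_N / (c_N + k_N) : 0.0;
    double r_X = r_X_max * (phi_c < m_N ? phi_c : m_N);
    double r_N = r_X / y_X_N;                      /* g nitrate / g DW / d */
    double r_p = (c_N + k_p > 0) ? r_p_max * c_N / (c_N + k_p) : 0.0;

    double D = 0.0, F = 0.0, removal = 0.0;
    if (mode == 1) {                               /* fed-batch: D = F/V */
        F = F_flow;
        D = (V > 0) ? F / V : 0.0;
    } else if (mode == 2) {                        /* semi-continuous rate */
        D = D_conf;
        removal = D_conf;
    }

    ydot[0] = r_X * c_X - D * c_X;
    ydot[1] = -1000.0 * r_N * c_X + D * (c_N_f - c_N);
    ydot[2] = (r_p - k_pd * c_P) * c_X - D * c_P;
    ydot[3] = F;
    ydot[4] = removal * c_X * V;
    ydot[5] = removal * c_P * V;
}
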